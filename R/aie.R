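#' Accuracy improvement efficiency
#'
#' The relative OKC increment of a classification over the baseline level,
#' `AIE = (OKC - OKC_min) / OKC_min`. Zero at the baseline, strictly
#' increasing in OKC for a fixed baseline.
#'
#' @param okc overall kappa of the classification under study.
#' @param okc_min baseline overall kappa (> 0): by convention the minimum
#'   OKC among classifications of the plain multispectral dataset.
#' @return the improvement ratio (multiply by 100 for percent).
#' @export
aie <- function(okc, okc_min) {
  if (any(okc_min <= 0)) stop("okc_min must be > 0")
  (okc - okc_min) / okc_min
}

#' Assemble a classifier-by-dataset AIE table
#'
#' Rows of (classifier, dataset, okc_type, okc) gain an `aie` column.
#' `okc_type` is `"performance"` for training-sample reports and
#' `"accuracy"` for test-sample reports; the baseline `okc_min` of each
#' type is the minimum OKC among the rows of that type whose dataset is
#' the baseline dataset (default `"HMS"`, the plain multispectral scheme).
#'
#' @param reports either a list of `accuracy_report`s or a data frame with
#'   columns `classifier`, `dataset`, `okc_type` (or `role`), `okc`.
#' @param baseline_dataset dataset name defining the baseline (default
#'   `"HMS"`).
#' @return data frame of class `aie_table` with columns `classifier`,
#'   `dataset`, `okc_type`, `okc`, `aie`; per-type baselines attached as
#'   attribute `okc_min`.
#' @export
build_aie_table <- function(reports, baseline_dataset = "HMS") {
  if (is.data.frame(reports)) {
    df <- reports
    if (!"okc_type" %in% names(df)) {
      if (!"role" %in% names(df)) stop("need `okc_type` or `role` column")
      df$okc_type <- ifelse(df$role == "training", "performance", "accuracy")
    }
  } else {
    df <- do.call(rbind, lapply(reports, function(r) data.frame(
      classifier = r$classifier, dataset = r$dataset,
      okc_type = if (r$role == "training") "performance" else "accuracy",
      okc = r$okc, stringsAsFactors = FALSE)))
  }
  base <- df[df$dataset == baseline_dataset, ]
  if (nrow(base) == 0)
    stop("no rows for baseline dataset '", baseline_dataset, "'")
  okc_min <- tapply(base$okc, base$okc_type, min)
  if (any(okc_min <= 0))
    stop("baseline OKC must be positive to define AIE")
  df$aie <- aie(df$okc, unname(okc_min[df$okc_type]))
  attr(df, "okc_min") <- okc_min
  class(df) <- c("aie_table", "data.frame")
  df
}

#' Two-way factorial ANOVA of AIE
#'
#' Balanced fixed-effects dataset x classifier ANOVA with interaction,
#' `Y = b0 + b1 X1 + b2 X2 + b12 X1X2 + e`, fitted by [stats::aov()]. The
#' two OKC types (training-performance AIE and test-accuracy AIE) serve as
#' the replicates of each cell; without replication the interaction is not
#' estimable and an error suggests the additive model.
#'
#' @param table an `aie_table` (or data frame with `dataset`, `classifier`,
#'   `aie`).
#' @param interaction fit the interaction term (default TRUE).
#' @param alpha significance level used for flagging terms (default 0.05).
#' @return object of class `anova_result`: list with `table` (term, df,
#'   sum_sq, mean_sq, f, p, significant), `effects` (model coefficients),
#'   `residual_df`, `residual_ms`, `alpha`, and the fitted `aov` object.
#' @export
two_way_anova <- function(table, interaction = TRUE, alpha = 0.05) {
  df <- as.data.frame(table)
  for (v in c("dataset", "classifier", "aie"))
    if (!v %in% names(df)) stop("missing column `", v, "`")
  df$dataset <- factor(df$dataset)
  df$classifier <- factor(df$classifier)
  if (nlevels(df$dataset) < 2L || nlevels(df$classifier) < 2L)
    stop("need at least 2 levels per factor")
  reps <- table(df$dataset, df$classifier)
  if (interaction && any(reps < 2L))
    stop("interaction requested without replication (",
         "some cells have < 2 observations); fit the additive model ",
         "with interaction = FALSE")
  fml <- if (interaction) aie ~ dataset * classifier else aie ~ dataset + classifier
  fit <- stats::aov(fml, data = df)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  resid_row <- terms == "Residuals"
  out <- data.frame(term = terms[!resid_row],
                    df = sm$Df[!resid_row],
                    sum_sq = sm$`Sum Sq`[!resid_row],
                    mean_sq = sm$`Mean Sq`[!resid_row],
                    f = sm$`F value`[!resid_row],
                    p = sm$`Pr(>F)`[!resid_row],
                    stringsAsFactors = FALSE)
  # zero-variance terms (constant data leave only rounding noise in the
  # sums of squares): define F = 0, p = 1 rather than 0/0 or noise ratios
  tiny <- 1e-10 * max(mean(df$aie^2) * nrow(df), .Machine$double.eps)
  degenerate <- out$sum_sq <= tiny & (!is.finite(out$f) | sm$`Sum Sq`[resid_row] <= tiny)
  out$f[degenerate] <- 0
  out$p[degenerate] <- 1
  out$p[is.infinite(out$f)] <- 0
  out$significant <- out$p <= alpha
  structure(list(table = out, effects = stats::coef(fit),
                 residual_df = sm$Df[resid_row],
                 residual_ms = sm$`Mean Sq`[resid_row],
                 total_ss = sum(sm$`Sum Sq`),
                 alpha = alpha, fit = fit),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Residuals: df=%d, MS=%.5g\n", x$residual_df, x$residual_ms))
  invisible(x)
}

duncan_critical_range <- function(p, df_error, n_per_mean, ms_error, alpha) {
  # Duncan protection level for a stretch of p means
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  stats::qtukey(1 - alpha_p, p, df_error) * sqrt(ms_error / n_per_mean)
}

#' Duncan's new multiple range grouping
#'
#' Post hoc grouping of level means after an ANOVA. Means are sorted in
#' descending order; a stretch of p consecutive means is homogeneous when
#' its extremes differ by no more than the critical range
#' `q(alpha_p, p, df_error) * sqrt(ms_error / n_per_mean)` at the Duncan
#' protection level `alpha_p = 1 - (1 - alpha)^(p - 1)`. Maximal
#' homogeneous stretches receive group letters; levels sharing a letter are
#' not significantly different at `alpha`.
#'
#' @param cell_means named numeric vector of level means.
#' @param ms_error residual mean square from the ANOVA.
#' @param df_error residual degrees of freedom (>= 1).
#' @param n_per_mean observations behind each mean.
#' @param alpha significance level (default 0.05).
#' @return object of class `duncan_grouping`: data frame `groups` with
#'   columns `level`, `mean`, `letters` (descending by mean), plus the
#'   critical ranges used.
#' @export
duncan_groups <- function(cell_means, ms_error, df_error, n_per_mean,
                          alpha = 0.05) {
  if (ms_error <= 0) stop("ms_error must be > 0")
  if (df_error < 1) stop("df_error must be >= 1")
  k <- length(cell_means)
  if (is.null(names(cell_means))) names(cell_means) <- paste0("L", seq_len(k))
  ord <- order(cell_means, decreasing = TRUE)
  m <- cell_means[ord]
  ranges <- c(NA, vapply(2:max(2, k), function(p)
    duncan_critical_range(p, df_error, n_per_mean, ms_error, alpha),
    numeric(1)))
  # homogeneous stretches: extremes within the critical range for their span
  homog <- function(i, j) (m[i] - m[j]) <= ranges[j - i + 1]
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && homog(i, j + 1)) j <- j + 1
    intervals[[i]] <- c(i, j)
  }
  # keep maximal intervals only
  keep <- rep(TRUE, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a != b && keep[a] &&
        intervals[[b]][1] <= intervals[[a]][1] &&
        intervals[[b]][2] >= intervals[[a]][2] &&
        !identical(intervals[[b]], intervals[[a]])) keep[a] <- FALSE
  }
  ivs <- unique(intervals[keep])
  letters_vec <- rep("", k)
  for (g in seq_along(ivs)) {
    span <- ivs[[g]][1]:ivs[[g]][2]
    letters_vec[span] <- paste0(letters_vec[span], letters[g])
  }
  groups <- data.frame(level = names(m), mean = unname(m),
                       letters = letters_vec, stringsAsFactors = FALSE)
  structure(list(groups = groups, alpha = alpha,
                 critical_ranges = ranges[-1]),
            class = "duncan_grouping")
}

#' @export
print.duncan_grouping <- function(x, ...) {
  cat(sprintf("<duncan_grouping> alpha=%.3g\n", x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Duncan grouping of AIE means for one factor
#'
#' Convenience wrapper: group the per-level mean AIE of `"dataset"` or
#' `"classifier"` using the residual mean square of the fitted two-way
#' ANOVA.
#'
#' @param table an `aie_table`.
#' @param anova matching `anova_result` from [two_way_anova()].
#' @param factor `"dataset"` or `"classifier"`.
#' @param alpha significance level.
#' @return a `duncan_grouping`.
#' @export
duncan_aie <- function(table, anova, factor = c("dataset", "classifier"),
                       alpha = 0.05) {
  factor <- match.arg(factor)
  means <- tapply(table$aie, table[[factor]], mean)
  n_per <- nrow(table) / length(means)
  duncan_groups(stats::setNames(as.numeric(means), names(means)),
                ms_error = anova$residual_ms, df_error = anova$residual_df,
                n_per_mean = n_per, alpha = alpha)
}
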