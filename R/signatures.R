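#' Train per-species Gaussian signatures
#'
#' For every species in a sample set, the sample mean vector and sample
#' covariance (n - 1 denominator) over the feature bands. A covariance that
#' is ill-conditioned (reciprocal condition number below 1e-8, including
#' the all-identical-pixels case) is regularized by adding
#' `lambda * (trace / B) * I` (or `lambda * I` when the trace is zero).
#'
#' @param samples a `sample_set` from [extract_samples()].
#' @param lambda ridge regularization weight (default 1e-6).
#' @return list of `class_signature` objects, ordered by species code; each
#'   has fields `species_code`, `mean`, `cov`, `n`, `band_names`.
#' @export
train_signatures <- function(samples, lambda = 1e-6) {
  stopifnot(inherits(samples, "sample_set"))
  B <- ncol(samples$features)
  codes <- sort(unique(samples$codes))
  too_few <- codes[vapply(codes, function(cc) sum(samples$codes == cc) <= B,
                          logical(1))]
  if (length(too_few))
    stop("species with too few training pixels (need n > ", B, " bands): ",
         paste(too_few, collapse = ", "))
  lapply(codes, function(cc) {
    X <- samples$features[samples$codes == cc, , drop = FALSE]
    S <- stats::cov(X)
    S <- regularize_cov(S, lambda)
    structure(list(species_code = cc, mean = colMeans(X), cov = S,
                   n = nrow(X), band_names = samples$band_names),
              class = "class_signature")
  })
}

regularize_cov <- function(S, lambda = 1e-6) {
  B <- nrow(S)
  S <- (S + t(S)) / 2
  if (rcond_sym(S) < 1e-8) {
    tr <- sum(diag(S))
    ridge <- if (tr > 0) lambda * (tr / B) else lambda
    S <- S + diag(ridge, B)
  }
  S
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  mn <- min(ev)
  if (mn <= 0) return(0)
  mn / max(ev)
}

#' @export
print.class_signature <- function(x, ...) {
  cat(sprintf("<class_signature> species %d, %d bands, n=%d\n",
              x$species_code, length(x$mean), x$n))
  invisible(x)
}

#' Transformed divergence between two Gaussian signatures
#'
#' The divergence between two multivariate normal class models,
#' \deqn{D = \tfrac12 tr[(\Sigma_1-\Sigma_2)(\Sigma_2^{-1}-\Sigma_1^{-1})]
#'     + \tfrac12 tr[(\Sigma_1^{-1}+\Sigma_2^{-1})
#'       (\mu_1-\mu_2)(\mu_1-\mu_2)^T],}
#' rescaled onto the saturating 0-2000 separability scale
#' `TD = 2000 (1 - exp(-D / 8))`. TD = 0 for identical signatures and
#' approaches 2000 as the classes become fully separable.
#'
#' @param s1,s2 `class_signature` objects of equal dimensionality.
#' @return the transformed divergence, in [0, 2000].
#' @export
transformed_divergence <- function(s1, s2) {
  stopifnot(inherits(s1, "class_signature"), inherits(s2, "class_signature"))
  if (length(s1$mean) != length(s2$mean))
    stop("signatures have different dimensionality")
  S1 <- regularize_cov(s1$cov); S2 <- regularize_cov(s2$cov)
  P1 <- solve(S1); P2 <- solve(S2)
  dm <- s1$mean - s2$mean
  D <- 0.5 * sum(diag((S1 - S2) %*% (P2 - P1))) +
       0.5 * sum(diag((P1 + P2) %*% (dm %o% dm)))
  2000 * (1 - exp(-D / 8))
}

#' Pairwise transformed-divergence matrix
#'
#' All pairwise separabilities of a signature list, with each pair graded
#' on the conventional scale: `separable` (TD = 2000 within rounding),
#' `good` (1900 <= TD < 2000) and `poor` (TD < 1900).
#'
#' @param sigs list of `class_signature` objects (>= 2).
#' @return object of class `td_matrix`: list with `codes`, `td` (symmetric
#'   K x K matrix, zero diagonal) and `grade` (character K x K matrix).
#' @export
td_matrix <- function(sigs) {
  if (length(sigs) < 2L) stop("need at least two signatures")
  codes <- vapply(sigs, `[[`, numeric(1), "species_code")
  K <- length(codes)
  td <- matrix(0, K, K, dimnames = list(codes, codes))
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    td[i, j] <- td[j, i] <- transformed_divergence(sigs[[i]], sigs[[j]])
  }
  grade <- matrix("", K, K, dimnames = dimnames(td))
  grade[round(td) >= 2000] <- "separable"
  grade[round(td) < 2000 & td >= 1900] <- "good"
  grade[td < 1900] <- "poor"
  diag(grade) <- ""
  structure(list(codes = codes, td = td, grade = grade), class = "td_matrix")
}

#' @export
print.td_matrix <- function(x, ...) {
  off <- x$td[upper.tri(x$td)]
  cat(sprintf("<td_matrix> %d species; TD range [%.0f, %.0f]; %d/%d pairs below 1900\n",
              length(x$codes), min(off), max(off), sum(off < 1900), length(off)))
  invisible(x)
}

#' Export a TD matrix as CSV
#'
#' Values rounded to integers, species abbreviations as headers when a
#' species table is given.
#'
#' @param x a `td_matrix`.
#' @param path output CSV path.
#' @param species_table optional table mapping `code` to `abbrev`.
#' @return `path`, invisibly.
#' @export
write_td_csv <- function(x, path, species_table = NULL) {
  m <- round(x$td)
  if (!is.null(species_table)) {
    ab <- species_table$abbrev[match(x$codes, species_table$code)]
    dimnames(m) <- list(ab, ab)
  }
  utils::write.csv(m, path)
  invisible(path)
}
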