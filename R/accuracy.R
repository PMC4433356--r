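#' Error (confusion) matrix
#'
#' Tallies predicted-vs-reference species counts: `counts[i, j]` is the
#' number of pixels predicted as species i whose reference label is j
#' (rows = predicted map, columns = reference). Only reference-labeled
#' pixels with a nonzero prediction are counted. The species axis is the
#' union of the reference species table and any predicted codes, so K is
#' stable across reports even when a species is never predicted.
#'
#' @param predicted a `classification_result` (or integer label matrix).
#' @param reference a `label_raster` of matching shape.
#' @param codes optional explicit species-code axis.
#' @return object of class `error_matrix`: list with `codes`, `counts`
#'   (K x K integer), `n`.
#' @export
error_matrix <- function(predicted, reference, codes = NULL) {
  pred <- if (inherits(predicted, "classification_result"))
    predicted$label_map else predicted
  stopifnot(inherits(reference, "label_raster"), is.matrix(pred))
  ref <- reference$labels
  if (!identical(dim(pred), dim(ref)))
    stop("predicted and reference shapes differ")
  keep <- ref > 0L & pred > 0L
  if (!any(keep)) stop("no countable pixels (no labeled, classified overlap)")
  if (is.null(codes))
    codes <- sort(unique(c(reference$species_table$code,
                           pred[keep], ref[keep])))
  f <- function(v) factor(v, levels = codes)
  counts <- table(predicted = f(pred[keep]), reference = f(ref[keep]))
  counts <- matrix(as.integer(counts), length(codes), length(codes),
                   dimnames = list(predicted = codes, reference = codes))
  structure(list(codes = codes, counts = counts, n = sum(counts)),
            class = "error_matrix")
}

#' @export
print.error_matrix <- function(x, ...) {
  cat(sprintf("<error_matrix> %d species, n=%d, overall accuracy %.3f\n",
              length(x$codes), x$n, sum(diag(x$counts)) / x$n))
  invisible(x)
}

#' Overall kappa coefficient
#'
#' Chance-corrected overall agreement
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / n` and chance agreement
#' `p_e = sum_i row_i * col_i / n^2`. When `p_e = 1` (all mass in one
#' cell) kappa is defined as 0 with a warning.
#'
#' @param m an `error_matrix` (or plain square count matrix).
#' @return kappa in [-1, 1].
#' @export
overall_kappa <- function(m) {
  counts <- if (inherits(m, "error_matrix")) m$counts else m
  n <- sum(counts)
  if (n <= 0) stop("empty error matrix")
  po <- sum(diag(counts)) / n
  pe <- sum(rowSums(counts) * colSums(counts)) / n^2
  if (pe >= 1) {
    warning("degenerate error matrix (chance agreement = 1); kappa set to 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Overall accuracy
#'
#' @param m an `error_matrix` (or plain square count matrix).
#' @return trace / n.
#' @export
overall_accuracy <- function(m) {
  counts <- if (inherits(m, "error_matrix")) m$counts else m
  sum(diag(counts)) / sum(counts)
}

#' User's-accuracy conditional kappa for one species
#'
#' Chance-corrected user's accuracy of the map class i:
#' `(n n_ii - n_i+ n_+i) / (n n_i+ - n_i+ n_+i)` with `n_i+` the predicted
#' row total and `n_+i` the reference column total. Undefined (NA) when the
#' species was never predicted.
#'
#' @param m an `error_matrix`.
#' @param code species code.
#' @return conditional kappa (<= 1), or `NA` when the row total is zero.
#' @export
conditional_kappa_user <- function(m, code) {
  stopifnot(inherits(m, "error_matrix"))
  i <- match(code, m$codes)
  if (is.na(i)) stop("species code ", code, " not in the error matrix")
  n <- m$n
  ni_ <- sum(m$counts[i, ])
  n_i <- sum(m$counts[, i])
  if (ni_ == 0) return(NA_real_)
  den <- n * ni_ - ni_ * n_i
  if (den == 0) {
    warning("chance-saturated row for species ", code, "; conditional kappa set to 0")
    return(0)
  }
  (n * m$counts[i, i] - ni_ * n_i) / den
}

#' Full accuracy report for one classification
#'
#' Overall kappa, overall accuracy and the per-species conditional kappa
#' vector, tagged with classifier, dataset and sample role. The paper-style
#' summary of one classifier x dataset x sample-role cell.
#'
#' @param predicted a `classification_result`.
#' @param reference a `label_raster`.
#' @param classifier,dataset,role metadata tags (default from inputs).
#' @return object of class `accuracy_report`: list with `okc`,
#'   `overall_accuracy`, `sckc` (named per-species vector), `n`,
#'   `classifier`, `dataset`, `role`, `error_matrix`.
#' @export
accuracy_report <- function(predicted, reference,
                            classifier = NULL, dataset = NULL, role = NULL) {
  m <- error_matrix(predicted, reference)
  if (is.null(classifier))
    classifier <- if (inherits(predicted, "classification_result"))
      predicted$classifier else "unknown"
  if (is.null(dataset))
    dataset <- if (inherits(predicted, "classification_result"))
      predicted$dataset else ""
  if (is.null(role)) role <- reference$role
  sckc <- vapply(m$codes, function(cc) conditional_kappa_user(m, cc),
                 numeric(1))
  names(sckc) <- m$codes
  structure(list(okc = overall_kappa(m),
                 overall_accuracy = overall_accuracy(m),
                 sckc = sckc, n = m$n, classifier = classifier,
                 dataset = dataset, role = role, error_matrix = m),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %s / %s / %s: OKC %.4f, OA %.4f, n=%d\n",
              x$classifier, x$dataset, x$role, x$okc, x$overall_accuracy, x$n))
  invisible(x)
}

#' Export an accuracy report as CSV
#'
#' One row per species (conditional kappa) plus a summary row with the
#' overall kappa and overall accuracy.
#'
#' @param x an `accuracy_report`.
#' @param path output CSV path.
#' @param species_table optional code-to-abbreviation table.
#' @return `path`, invisibly.
#' @export
write_accuracy_csv <- function(x, path, species_table = NULL) {
  ab <- names(x$sckc)
  if (!is.null(species_table)) {
    i <- match(as.integer(names(x$sckc)), species_table$code)
    ab <- ifelse(is.na(i), names(x$sckc), species_table$abbrev[i])
  }
  df <- data.frame(species = c(ab, "OVERALL"),
                   statistic = c(rep("SCKC", length(x$sckc)), "OKC"),
                   value = c(unname(x$sckc), x$okc))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Classification uncertainty
#'
#' The loss of chance-corrected agreement between training and independent
#' test samples: training OKC minus test OKC. Antisymmetric under swapping
#' the two reports.
#'
#' @param training,test `accuracy_report`s for the same classifier/dataset.
#' @return a single number.
#' @export
classification_uncertainty <- function(training, test) {
  training$okc - test$okc
}
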