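#' Pixel classification result
#'
#' @description
#' Classifiers return a `classification_result`: an integer `label_map`
#' (0 = nodata / unclassifiable), an optional `score_map` of the winning
#' score, and the classifier / dataset names. Shape matches the input
#' stack; every label is a trained species code or 0.
#'
#' @name classification_result
NULL

classification_result <- function(label_map, score_map, classifier,
                                  dataset = "") {
  structure(list(label_map = label_map, score_map = score_map,
                 classifier = classifier, dataset = dataset),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s%s: %d x %d, %d classified pixels\n",
              x$classifier, if (nzchar(x$dataset)) paste0(" on ", x$dataset) else "",
              nrow(x$label_map), ncol(x$label_map), sum(x$label_map > 0L)))
  invisible(x)
}

check_sigs <- function(stack_or_X, sigs) {
  B <- if (is.matrix(stack_or_X)) ncol(stack_or_X) else n_bands(stack_or_X)
  for (s in sigs)
    if (length(s$mean) != B)
      stop("signature dimension (", length(s$mean),
           ") does not match band count (", B, ")")
  ord <- order(vapply(sigs, `[[`, numeric(1), "species_code"))
  sigs[ord]   # ties break toward the lowest species code downstream
}

# assemble a result from per-pixel labels/scores in row-major order
wrap_result <- function(stack, labels, scores, classifier, dataset = "") {
  d <- dim(stack$data)
  lab <- matrix(labels, d[1], d[2], byrow = TRUE)
  sc <- matrix(scores, d[1], d[2], byrow = TRUE)
  lab[stack$mask] <- 0L
  sc[stack$mask] <- NA_real_
  classification_result(lab, sc, classifier, dataset)
}

valid_rows <- function(stack) {
  X <- band_matrix(stack)
  keep <- stats::complete.cases(X) & !as.vector(t(stack$mask))
  list(X = X, keep = keep)
}

# --- maximum likelihood -----------------------------------------------------

mlc_discriminants <- function(X, sigs, priors) {
  K <- length(sigs)
  G <- matrix(-Inf, nrow(X), K)
  for (i in seq_len(K)) {
    S <- regularize_cov(sigs[[i]]$cov)
    ch <- chol(S)
    logdet <- 2 * sum(log(diag(ch)))
    Z <- forwardsolve(t(ch), t(sweep(X, 2, sigs[[i]]$mean)))
    d2 <- colSums(Z * Z)
    G[, i] <- log(priors[i]) - 0.5 * logdet - 0.5 * d2
  }
  G
}

#' Maximum likelihood classification
#'
#' Gaussian maximum likelihood: each pixel is assigned the class maximising
#' `ln p_i - ln|Sigma_i|/2 - (x - mu_i)' Sigma_i^{-1} (x - mu_i)/2`. Equal
#' priors unless given. Ties break toward the lowest species code.
#'
#' @param stack feature `raster_stack`.
#' @param sigs list of `class_signature` objects.
#' @param priors optional per-class prior weights (normalised internally),
#'   in species-code order.
#' @return a `classification_result`.
#' @export
classify_mlc <- function(stack, sigs, priors = NULL) {
  sigs <- check_sigs(stack, sigs)
  K <- length(sigs)
  if (is.null(priors)) priors <- rep(1 / K, K)
  if (length(priors) != K || any(priors <= 0)) stop("invalid priors")
  priors <- priors / sum(priors)
  v <- valid_rows(stack)
  codes <- vapply(sigs, `[[`, numeric(1), "species_code")
  G <- mlc_discriminants(v$X[v$keep, , drop = FALSE], sigs, priors)
  win <- max.col(G, ties.method = "first")
  labels <- integer(length(v$keep)); scores <- rep(NA_real_, length(v$keep))
  labels[v$keep] <- as.integer(codes[win])
  scores[v$keep] <- G[cbind(seq_len(nrow(G)), win)]
  wrap_result(stack, labels, scores, "mlc")
}

# --- Mahalanobis distance ---------------------------------------------------

#' Mahalanobis distance classification
#'
#' Minimum Mahalanobis distance to the class means under a pooled
#' covariance (the n-weighted average of the class covariances). With an
#' identity pooled covariance this reduces to nearest Euclidean mean.
#'
#' @inheritParams classify_mlc
#' @return a `classification_result`.
#' @export
classify_md <- function(stack, sigs) {
  sigs <- check_sigs(stack, sigs)
  ns <- vapply(sigs, `[[`, numeric(1), "n")
  Sp <- Reduce(`+`, Map(function(s, w) w * s$cov, sigs, ns)) / sum(ns)
  Sp <- regularize_cov(Sp)
  P <- tryCatch(solve(Sp), error = function(e)
    stop("singular pooled covariance: ", conditionMessage(e)))
  v <- valid_rows(stack)
  X <- v$X[v$keep, , drop = FALSE]
  K <- length(sigs)
  D <- matrix(Inf, nrow(X), K)
  for (i in seq_len(K)) {
    dx <- sweep(X, 2, sigs[[i]]$mean)
    D[, i] <- rowSums((dx %*% P) * dx)
  }
  win <- max.col(-D, ties.method = "first")
  codes <- vapply(sigs, `[[`, numeric(1), "species_code")
  labels <- integer(length(v$keep)); scores <- rep(NA_real_, length(v$keep))
  labels[v$keep] <- as.integer(codes[win])
  scores[v$keep] <- D[cbind(seq_len(nrow(D)), win)]
  wrap_result(stack, labels, scores, "md")
}

# --- spectral angle mapper --------------------------------------------------

#' Spectral angle mapper classification
#'
#' Assigns each pixel the class whose mean spectrum subtends the smallest
#' angle `arccos(x . mu / (|x| |mu|))`; invariant to positive per-pixel
#' rescaling of the spectrum. Zero-norm pixels are masked in the output.
#'
#' @inheritParams classify_mlc
#' @return a `classification_result`.
#' @export
classify_sam <- function(stack, sigs) {
  sigs <- check_sigs(stack, sigs)
  for (s in sigs) if (sqrt(sum(s$mean^2)) == 0)
    stop("zero-norm mean vector for species ", s$species_code)
  v <- valid_rows(stack)
  X <- v$X[v$keep, , drop = FALSE]
  xn <- sqrt(rowSums(X * X))
  nz <- xn > 0
  K <- length(sigs)
  A <- matrix(Inf, nrow(X), K)
  for (i in seq_len(K)) {
    mu <- sigs[[i]]$mean
    cosang <- (X %*% mu) / (xn * sqrt(sum(mu^2)))
    A[, i] <- acos(pmin(pmax(cosang, -1), 1))
  }
  win <- max.col(-A, ties.method = "first")
  codes <- vapply(sigs, `[[`, numeric(1), "species_code")
  labels <- integer(length(v$keep)); scores <- rep(NA_real_, length(v$keep))
  lab_v <- as.integer(codes[win]); lab_v[!nz] <- 0L
  sc_v <- A[cbind(seq_len(nrow(A)), win)]; sc_v[!nz] <- NA_real_
  labels[v$keep] <- lab_v
  scores[v$keep] <- sc_v
  wrap_result(stack, labels, scores, "sam")
}

# --- spectral information divergence ---------------------------------------

sid_pair <- function(p, q) sum(p * log(p / q)) + sum(q * log(q / p))

to_simplex <- function(M, eps = 1e-12) {
  M[M < eps] <- eps
  M / rowSums(M)
}

#' Spectral information divergence classification
#'
#' Treats each (nonnegative) spectrum as a probability distribution over
#' bands (values floored at `eps` before normalising) and assigns the class
#' minimising the symmetric information divergence
#' `SID(p, q) = sum p ln(p/q) + sum q ln(q/p)`. All-zero spectra are masked.
#'
#' @inheritParams classify_mlc
#' @param eps floor applied to zeros before simplex normalisation.
#' @return a `classification_result`.
#' @export
classify_sid <- function(stack, sigs, eps = 1e-12) {
  sigs <- check_sigs(stack, sigs)
  v <- valid_rows(stack)
  X <- v$X[v$keep, , drop = FALSE]
  allzero <- rowSums(abs(X)) == 0
  P <- to_simplex(X, eps)
  K <- length(sigs)
  D <- matrix(Inf, nrow(X), K)
  # SID(p,q) = sum_j [p ln p - p ln q + q ln q - q ln p]
  for (i in seq_len(K)) {
    q <- as.vector(to_simplex(matrix(sigs[[i]]$mean, 1), eps))
    D[, i] <- rowSums(P * log(P)) - P %*% log(q) +
              sum(q * log(q)) - log(P) %*% q
  }
  win <- max.col(-D, ties.method = "first")
  codes <- vapply(sigs, `[[`, numeric(1), "species_code")
  labels <- integer(length(v$keep)); scores <- rep(NA_real_, length(v$keep))
  lab_v <- as.integer(codes[win]); lab_v[allzero] <- 0L
  sc_v <- D[cbind(seq_len(nrow(D)), win)]; sc_v[allzero] <- NA_real_
  labels[v$keep] <- lab_v
  scores[v$keep] <- sc_v
  wrap_result(stack, labels, scores, "sid")
}

# --- dispatch ---------------------------------------------------------------

#' Classify a stack by name, including external plug-in learners
#'
#' Dispatches to the native classifiers (`"mlc"`, `"md"`, `"sam"`, `"sid"`)
#' or to a user-supplied plug-in. A plug-in is a function
#' `function(train_samples, X)` receiving the training `sample_set` and the
#' pixel-by-band feature matrix of the unmasked pixels, and returning one
#' label per row; this is how off-the-shelf learners (support vector
#' machines, neural networks, ...) join the comparison without the package
#' importing them.
#'
#' @param stack feature `raster_stack`.
#' @param sigs list of `class_signature` objects (native methods).
#' @param method one of `"mlc"`, `"md"`, `"sam"`, `"sid"`, `"plugin"`.
#' @param plugin plug-in function (required for `method = "plugin"`).
#' @param train_samples training `sample_set` handed to the plug-in.
#' @param ... passed to the native classifier.
#' @return a `classification_result`.
#' @export
classify <- function(stack, sigs = NULL,
                     method = c("mlc", "md", "sam", "sid", "plugin"),
                     plugin = NULL, train_samples = NULL, ...) {
  method <- match.arg(method)
  if (method == "plugin") {
    if (!is.function(plugin)) stop("method 'plugin' needs a plug-in function")
    v <- valid_rows(stack)
    X <- v$X[v$keep, , drop = FALSE]
    labels_sub <- plugin(train_samples, X)
    if (length(labels_sub) != nrow(X))
      stop("plug-in contract violation: returned ", length(labels_sub),
           " labels for ", nrow(X), " pixels")
    labels <- integer(length(v$keep))
    labels[v$keep] <- as.integer(labels_sub)
    return(wrap_result(stack, labels, rep(NA_real_, length(v$keep)),
                       "plugin"))
  }
  switch(method,
         mlc = classify_mlc(stack, sigs, ...),
         md  = classify_md(stack, sigs),
         sam = classify_sam(stack, sigs),
         sid = classify_sid(stack, sigs, ...))
}
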