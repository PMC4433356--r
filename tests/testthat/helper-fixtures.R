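# shared fixtures and independent oracles used across the suite

# small 4-band reflectance stack with deterministic values
tiny_refl_stack <- function(rows = 6, cols = 5, seed = 7) {
  set.seed(seed)
  a <- array(runif(rows * cols * 4, 0.02, 0.6), c(rows, cols, 4))
  raster_stack(a, band_names = c("blue", "green", "red", "nir"),
               pixel_size = 2.4)
}

# single-pixel reflectance stack (handy for hand-value checks)
pixel_stack <- function(blue, green, red, nir) {
  raster_stack(array(c(blue, green, red, nir), c(1, 1, 4)),
               band_names = c("blue", "green", "red", "nir"))
}

tiny_species_table <- function(K) {
  data.frame(code = seq_len(K), abbrev = paste0("sp", seq_len(K)),
             name = paste("species", seq_len(K)), stringsAsFactors = FALSE)
}

# Gaussian training clouds for K classes; returns sample_set-like object
gaussian_samples <- function(means, sds, n, seed = 1, role = "training") {
  set.seed(seed)
  K <- nrow(means); B <- ncol(means)
  X <- do.call(rbind, lapply(seq_len(K), function(k)
    matrix(rnorm(n * B, mean = rep(means[k, ], each = n),
                 sd = rep(sds[k, ], each = n)), n, B)))
  codes <- rep(seq_len(K), each = n)
  structure(list(features = X, codes = codes,
                 counts = stats::setNames(rep(n, K), seq_len(K)),
                 band_names = paste0("b", seq_len(B)), role = role),
            class = "sample_set")
}

make_signature <- function(code, mean, cov, n = 100) {
  structure(list(species_code = code, mean = mean, cov = as.matrix(cov),
                 n = n, band_names = paste0("b", seq_along(mean))),
            class = "class_signature")
}

# stack wrapping a pixel-by-band matrix as a 1 x n image
matrix_stack <- function(X, band_names = paste0("b", seq_len(ncol(X)))) {
  a <- array(NA_real_, c(1, nrow(X), ncol(X)))
  for (b in seq_len(ncol(X))) a[1, , b] <- X[, b]
  raster_stack(a, band_names = band_names)
}

labels_of_result <- function(res) as.vector(res$label_map)

# --- independent nested-loop oracles ---------------------------------------

lee_sigma_oracle <- function(m, window, k, min_in_range = 1) {
  h <- (window - 1) / 2
  R <- nrow(m); C <- ncol(m)
  out <- m
  for (i in seq_len(R)) for (j in seq_len(C)) {
    if (is.na(m[i, j])) next
    vals <- as.vector(m[max(1, i - h):min(R, i + h),
                        max(1, j - h):min(C, j + h)])
    vals <- vals[!is.na(vals)]
    s <- if (length(vals) >= 2) stats::sd(vals) else 0
    inr <- vals[abs(vals - m[i, j]) <= k * s]
    out[i, j] <- if (length(inr) - 1 < min_in_range) m[i, j] else mean(inr)
  }
  out
}

mlc_oracle <- function(X, sigs, priors = NULL) {
  K <- length(sigs)
  if (is.null(priors)) priors <- rep(1 / K, K)
  codes <- sapply(sigs, `[[`, "species_code")
  apply(X, 1, function(x) {
    g <- sapply(seq_len(K), function(i) {
      S <- sigs[[i]]$cov
      log(priors[i]) - 0.5 * log(det(S)) -
        0.5 * t(x - sigs[[i]]$mean) %*% solve(S) %*% (x - sigs[[i]]$mean)
    })
    codes[which.max(g)]
  })
}

md_oracle <- function(X, sigs) {
  ns <- sapply(sigs, `[[`, "n")
  Sp <- Reduce(`+`, Map(function(s, w) w * s$cov, sigs, ns)) / sum(ns)
  Pi <- solve(Sp)
  codes <- sapply(sigs, `[[`, "species_code")
  apply(X, 1, function(x) {
    d <- sapply(sigs, function(s) t(x - s$mean) %*% Pi %*% (x - s$mean))
    codes[which.min(d)]
  })
}

sam_oracle <- function(X, sigs) {
  codes <- sapply(sigs, `[[`, "species_code")
  apply(X, 1, function(x) {
    a <- sapply(sigs, function(s)
      acos(sum(x * s$mean) / sqrt(sum(x^2) * sum(s$mean^2))))
    codes[which.min(a)]
  })
}

sid_oracle_pair <- function(x, mu, eps = 1e-12) {
  p <- pmax(x, eps); p <- p / sum(p)
  q <- pmax(mu, eps); q <- q / sum(q)
  sum(p * log(p / q)) + sum(q * log(q / p))
}

sid_oracle <- function(X, sigs) {
  codes <- sapply(sigs, `[[`, "species_code")
  apply(X, 1, function(x) {
    d <- sapply(sigs, function(s) sid_oracle_pair(x, s$mean))
    codes[which.min(d)]
  })
}

td_oracle <- function(m1, S1, m2, S2) {
  P1 <- solve(S1); P2 <- solve(S2)
  dm <- m1 - m2
  D <- 0.5 * sum(diag((S1 - S2) %*% (P2 - P1))) +
       0.5 * sum(diag((P1 + P2) %*% (dm %o% dm)))
  2000 * (1 - exp(-D / 8))
}

# Duncan oracle: two levels are NOT significantly different iff some stretch
# of the descending means containing both has extreme difference within the
# critical range for its span
duncan_share_oracle <- function(means, ms_error, df_error, n_per_mean, alpha) {
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  rng <- function(p) {
    ap <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - ap, p, df_error) * sqrt(ms_error / n_per_mean)
  }
  share <- matrix(FALSE, k, k, dimnames = list(names(m), names(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    lo <- min(i, j); hi <- max(i, j)
    found <- FALSE
    for (a in seq_len(lo)) for (b in hi:k) {
      if (b - a + 1 >= 2 && (m[a] - m[b]) <= rng(b - a + 1)) found <- TRUE
    }
    share[i, j] <- found || i == j
  }
  share
}
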