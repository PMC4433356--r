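three_class_sigs <- function(seed = 4, B = 3) {
  set.seed(seed)
  lapply(1:3, function(k) {
    A <- matrix(rnorm(B * B, sd = 0.3), B)
    make_signature(k, rnorm(B, mean = k, sd = 0.5),
                   crossprod(A) + diag(0.2, B), n = 40 + 10 * k)
  })
}

test_that("maximum likelihood equals the brute-force discriminant oracle", {
  sigs <- three_class_sigs()
  set.seed(10)
  X <- matrix(rnorm(300, mean = 2, sd = 1.2), 100, 3)
  got <- labels_of_result(classify_mlc(matrix_stack(X), sigs))
  expect_equal(got, unname(mlc_oracle(X, sigs)))
  # a pixel at a class mean of well-separated equal-covariance classes
  sep <- lapply(1:3, function(k) make_signature(k, c(10 * k, 0), diag(2)))
  at_mu <- matrix_stack(rbind(c(20, 0)))
  expect_equal(labels_of_result(classify_mlc(at_mu, sep)), 2L)
  # non-uniform priors shift the boundary the right way
  x_mid <- matrix_stack(rbind(c(15, 0)))
  heavy1 <- classify_mlc(x_mid, sep[1:2], priors = c(0.999999, 0.000001))
  expect_equal(labels_of_result(heavy1), 1L)
  expect_error(classify_mlc(matrix_stack(X[, 1:2]), sigs), "dimension")
})

test_that("Mahalanobis distance equals its oracle and known reductions", {
  sigs <- three_class_sigs(seed = 6)
  set.seed(11)
  X <- matrix(rnorm(300, 2, 1.5), 100, 3)
  got <- labels_of_result(classify_md(matrix_stack(X), sigs))
  expect_equal(got, unname(md_oracle(X, sigs)))
  # x at a class mean has distance zero
  at_mu <- matrix_stack(rbind(sigs[[2]]$mean))
  r <- classify_md(at_mu, sigs)
  expect_equal(labels_of_result(r), 2L)
  expect_equal(r$score_map[1, 1], 0, tolerance = 1e-10)
  # identity pooled covariance reduces to nearest Euclidean mean
  id_sigs <- lapply(1:3, function(k) make_signature(k, c(k, 2 * k), diag(2)))
  set.seed(12)
  Y <- matrix(runif(40, 0, 7), 20, 2)
  nearest <- apply(Y, 1, function(y)
    which.min(sapply(id_sigs, function(s) sum((y - s$mean)^2))))
  expect_equal(labels_of_result(classify_md(matrix_stack(Y), id_sigs)),
               unname(nearest))
  # equal covariances + equal priors: MLC and MD agree
  eq_sigs <- lapply(1:3, function(k) {
    make_signature(k, c(k, 5 - k), matrix(c(0.5, 0.1, 0.1, 0.3), 2), n = 50)
  })
  expect_equal(labels_of_result(classify_mlc(matrix_stack(Y), eq_sigs)),
               labels_of_result(classify_md(matrix_stack(Y), eq_sigs)))
})

test_that("spectral angle mapper is scale invariant and equals its oracle", {
  set.seed(13)
  sigs <- lapply(1:3, function(k)
    make_signature(k, abs(rnorm(4, k, 0.4)) + 0.05, diag(4)))
  X <- matrix(runif(400, 0.05, 1), 100, 4)
  got <- labels_of_result(classify_sam(matrix_stack(X), sigs))
  expect_equal(got, unname(sam_oracle(X, sigs)))
  # positive rescaling of each pixel leaves labels unchanged
  scl <- runif(100, 0.1, 9)
  expect_equal(labels_of_result(classify_sam(matrix_stack(X * scl), sigs)), got)
  # parallel pixel: angle 0; orthogonal mean: angle pi/2
  ortho <- list(make_signature(1, c(1, 0), diag(2)),
                make_signature(2, c(0, 1), diag(2)))
  r <- classify_sam(matrix_stack(rbind(c(3, 0))), ortho)
  expect_equal(labels_of_result(r), 1L)
  expect_equal(r$score_map[1, 1], 0, tolerance = 1e-7)
  # an all-zero pixel cannot be assigned an angle: masked out
  rz <- classify_sam(matrix_stack(rbind(c(0, 0), c(1, 1))), ortho)
  expect_equal(as.vector(rz$label_map), c(0L, 1L))
})

test_that("spectral information divergence: hand value, symmetry, oracle", {
  # 2-band p=(0.8,0.2) vs q=(0.5,0.5): SID = 0.3 ln 1.6 - 0.3 ln 0.4
  one <- list(make_signature(1, c(0.5, 0.5), diag(2)))
  r <- classify_sid(matrix_stack(rbind(c(0.8, 0.2))), one)
  expect_equal(r$score_map[1, 1], 0.3 * log(1.6) - 0.3 * log(0.4),
               tolerance = 1e-10)
  expect_equal(r$score_map[1, 1], 0.4159, tolerance = 1e-4)
  # symmetry on random simplex pairs
  set.seed(14)
  for (i in 1:25) {
    p <- runif(4); p <- p / sum(p)
    q <- runif(4); q <- q / sum(q)
    expect_equal(sid_oracle_pair(p, q), sid_oracle_pair(q, p),
                 tolerance = 1e-12)
  }
  # proportional spectrum has zero divergence to its class
  sigs <- lapply(1:3, function(k)
    make_signature(k, c(0.1 * k, 0.3, 0.6 - 0.1 * k, 0.2), diag(4)))
  rp <- classify_sid(matrix_stack(rbind(5 * sigs[[2]]$mean)), sigs)
  expect_equal(labels_of_result(rp), 2L)
  expect_equal(rp$score_map[1, 1], 0, tolerance = 1e-10)
  # full oracle equivalence on random nonnegative spectra
  X <- matrix(runif(400, 0, 1), 100, 4)
  expect_equal(labels_of_result(classify_sid(matrix_stack(X), sigs)),
               unname(sid_oracle(X, sigs)))
  # all-zero spectrum is masked
  rz <- classify_sid(matrix_stack(rbind(c(0, 0, 0, 0), c(0.2, 0.3, 0.1, 0.4))),
                     sigs)
  expect_equal(as.vector(rz$label_map)[1], 0L)
})

test_that("every unmasked pixel gets exactly one trained label", {
  sigs <- three_class_sigs(seed = 16)
  set.seed(17)
  a <- array(rnorm(6 * 7 * 3, 2, 1), c(6, 7, 3))
  a[2, 3, ] <- NA
  x <- raster_stack(a, paste0("b", 1:3))
  for (m in c("mlc", "md", "sam", "sid")) {
    r <- classify(x, sigs, method = m)
    expect_true(all(r$label_map[!x$mask] %in% 1:3), info = m)
    expect_equal(r$label_map[2, 3], 0L, info = m)
  }
})

test_that("MLC labels are invariant under consistent affine band transforms", {
  sigs <- three_class_sigs(seed = 18)
  set.seed(19)
  X <- matrix(rnorm(150, 2, 1), 50, 3)
  base <- labels_of_result(classify_mlc(matrix_stack(X), sigs))
  A <- matrix(c(2, 0.3, 0, -0.5, 1.5, 0.2, 0.1, 0, 0.8), 3)
  b <- c(1, -2, 0.5)
  Xt <- sweep(X %*% t(A), 2, b, `+`)
  sigs_t <- lapply(sigs, function(s)
    make_signature(s$species_code, as.vector(A %*% s$mean) + b,
                   A %*% s$cov %*% t(A), n = s$n))
  expect_equal(labels_of_result(classify_mlc(matrix_stack(Xt), sigs_t)), base)
})

test_that("dispatch and the plug-in contract behave", {
  sigs <- three_class_sigs(seed = 20)
  set.seed(21)
  x <- matrix_stack(matrix(rnorm(60, 2, 1), 20, 3))
  expect_equal(labels_of_result(classify(x, sigs, method = "mlc")),
               labels_of_result(classify_mlc(x, sigs)))
  const_plug <- function(train, X) rep(7L, nrow(X))
  r <- classify(x, method = "plugin", plugin = const_plug)
  expect_true(all(r$label_map == 7L))
  bad_plug <- function(train, X) 1L
  expect_error(classify(x, method = "plugin", plugin = bad_plug),
               "contract violation")
  expect_error(classify(x, sigs, method = "forest"), "arg")
})
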