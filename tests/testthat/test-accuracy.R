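em_from_counts <- function(counts) {
  codes <- seq_len(nrow(counts))
  structure(list(codes = codes,
                 counts = matrix(as.integer(counts), nrow(counts),
                                 dimnames = list(predicted = codes,
                                                 reference = codes)),
                 n = sum(counts)),
            class = "error_matrix")
}

test_that("error matrix equals a manual tally and conserves counts", {
  pred <- matrix(c(1, 1, 2, 2, 3, 3, 1, 2, 3), 3, byrow = TRUE)
  ref <- matrix(c(1, 2, 2, 2, 3, 1, 0, 2, 3), 3, byrow = TRUE)
  lr <- label_raster(ref, tiny_species_table(3), role = "test")
  m <- error_matrix(matrix(as.integer(pred), 3), lr)
  # manual tally over the 8 reference-labeled pixels
  expect_equal(m$counts["1", "1"], 1L)   # (1,1)
  expect_equal(m$counts["1", "2"], 1L)   # (1,2)
  expect_equal(m$counts["2", "2"], 3L)   # (1,3),(2,1),(3,2)
  expect_equal(m$counts["3", "1"], 1L)   # (2,3)
  expect_equal(m$counts["3", "3"], 2L)   # (3,1)... and (3,3)
  expect_equal(m$n, sum(ref > 0))
  # perfect prediction gives a diagonal matrix
  md <- error_matrix(matrix(as.integer(ref), 3), lr)
  expect_equal(sum(md$counts) - sum(diag(md$counts)), 0L)
  expect_error(error_matrix(matrix(0L, 3, 3), lr), "no countable pixels")
})

test_that("overall kappa identities: perfect, chance, hand-computed", {
  expect_equal(overall_kappa(em_from_counts(diag(c(10, 20, 5)))), 1)
  expect_equal(overall_kappa(em_from_counts(rbind(c(25, 25), c(25, 25)))), 0)
  expect_equal(overall_kappa(em_from_counts(rbind(c(40, 10), c(5, 45)))), 0.7)
  expect_warning(k0 <- overall_kappa(em_from_counts(matrix(7))), "degenerate")
  expect_equal(k0, 0)
})

test_that("conditional kappa: hand value, perfect rows, chance rows", {
  m <- em_from_counts(rbind(c(40, 10), c(5, 45)))
  expect_equal(conditional_kappa_user(m, 1), 1750 / 2750, tolerance = 1e-12)
  expect_equal(conditional_kappa_user(m, 1), 0.6364, tolerance = 1e-4)
  # row all on the diagonal: perfect user's accuracy
  mp <- em_from_counts(rbind(c(30, 0), c(10, 60)))
  expect_equal(conditional_kappa_user(mp, 1), 1)
  # row matching chance: zero
  mc <- em_from_counts(rbind(c(20, 20), c(30, 30)))
  expect_equal(conditional_kappa_user(mc, 1), 0)
  # never-predicted species is undefined
  mz <- em_from_counts(rbind(c(0, 0), c(10, 30)))
  expect_true(is.na(conditional_kappa_user(mz, 1)))
  expect_error(conditional_kappa_user(mz, 9), "not in the error matrix")
})

test_that("report composition matches its parts; permutations behave", {
  set.seed(23)
  ref <- matrix(sample(0:3, 100, TRUE), 10)
  pred <- ref
  flip <- sample(which(ref > 0), 12)
  pred[flip] <- (pred[flip] %% 3L) + 1L
  lr <- label_raster(matrix(as.integer(ref), 10), tiny_species_table(3),
                     role = "test")
  pm <- matrix(as.integer(pred), 10)
  rep <- accuracy_report(pm, lr, classifier = "mlc", dataset = "HMS",
                         role = "test")
  m <- error_matrix(pm, lr)
  expect_equal(rep$okc, overall_kappa(m))
  expect_equal(rep$overall_accuracy, overall_accuracy(m))
  expect_equal(rep$sckc[["2"]], conditional_kappa_user(m, 2))
  # permuting species codes leaves OKC unchanged, permutes SCKC
  perm <- c(3L, 1L, 2L)
  ref_p <- ref; pred_p <- pred
  ref_p[ref > 0] <- perm[ref[ref > 0]]
  pred_p[pred > 0] <- perm[pred[pred > 0]]
  lr_p <- label_raster(matrix(as.integer(ref_p), 10), tiny_species_table(3),
                       role = "test")
  rep_p <- accuracy_report(matrix(as.integer(pred_p), 10), lr_p)
  expect_equal(rep_p$okc, rep$okc)
  expect_equal(rep_p$sckc[[as.character(perm[2])]], rep$sckc[["2"]])
  # perfect classification: okc 1, all defined sckc 1
  rep_perf <- accuracy_report(matrix(as.integer(ref), 10), lr)
  expect_equal(rep_perf$okc, 1)
  expect_true(all(rep_perf$sckc[!is.na(rep_perf$sckc)] == 1))
  expect_equal(length(rep$sckc), 3L)
})

test_that("classification uncertainty is the antisymmetric OKC difference", {
  a <- list(okc = 0.9); b <- list(okc = 0.2)
  expect_equal(classification_uncertainty(a, b), 0.7)
  expect_equal(classification_uncertainty(b, a), -0.7)
})

test_that("species absent from prediction keep their zero row and column", {
  ref <- matrix(c(1L, 2L, 3L, 3L), 2)
  lr <- label_raster(ref, tiny_species_table(4), role = "test")
  m <- error_matrix(matrix(c(1L, 2L, 1L, 3L), 2), lr)
  expect_equal(m$codes, 1:4)                 # code 4 never seen, still there
  expect_equal(sum(m$counts[4, ]) + sum(m$counts[, 4]), 0L)
})
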