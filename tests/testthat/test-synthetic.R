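small_cfg <- function(seed, ...) {
  scene_config(n_species = 5L, ms_rows = 28L, ms_cols = 28L,
               crowns_per_species = 4L, crown_radius_range = c(5, 7),
               seed = seed, ...)
}

test_that("scene generation is bit-identical for a fixed seed", {
  a <- generate_scene(small_cfg(4))
  b <- generate_scene(small_cfg(4))
  expect_identical(a$ms$data, b$ms$data)
  expect_identical(a$pan$data, b$pan$data)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$truth$data, b$truth$data)
  c <- generate_scene(small_cfg(5))
  expect_false(identical(a$ms$data, c$ms$data))
})

test_that("with gaps and texture off, labeled pixels are exact species draws", {
  sc <- generate_scene(small_cfg(6, intra_gap_prob = 0, texture_amplitude = 0))
  ss <- extract_samples(sc$truth, sc$labels)
  cfg <- sc$config
  for (k in seq_len(cfg$n_species)) {
    X <- ss$features[ss$codes == k, , drop = FALSE]
    se <- cfg$species_sd / sqrt(nrow(X))
    expect_true(all(abs(colMeans(X) - cfg$species_means[k, ]) < 3.5 * se),
                info = paste("species", k))
    # per-band spread matches the generating sd (chi-square 99.9% band)
    for (b in 1:4) {
      ratio <- stats::sd(X[, b]) / cfg$species_sd[b]
      expect_true(ratio > 0.9 && ratio < 1.1)
    }
  }
})

test_that("species and gap bookkeeping are exact", {
  sc <- generate_scene(scene_config(n_species = 40L, ms_rows = 64L,
                                    ms_cols = 64L, crowns_per_species = 2L,
                                    crown_radius_range = c(4, 6), seed = 9))
  expect_equal(sort(unique(as.vector(sc$labels$labels[sc$labels$labels > 0]))),
               1:40)
  # gap pixels are unlabeled: a zero-gap scene labels every crown pixel more
  sc0 <- generate_scene(small_cfg(10, intra_gap_prob = 0))
  sc5 <- generate_scene(small_cfg(10, intra_gap_prob = 0.5))
  expect_gt(sum(sc0$labels$labels > 0), sum(sc5$labels$labels > 0))
})

test_that("stratified sampling is disjoint, exact and seeded", {
  sc <- generate_scene(small_cfg(11))
  for (seed in c(1, 2, 3)) {
    spl <- stratified_sample(sc$labels, counts = 40, split = 0.5, seed = seed)
    expect_true(all(spl$train$labels == 0L | spl$test$labels == 0L))
    tr_counts <- table(spl$train$labels[spl$train$labels > 0])
    te_counts <- table(spl$test$labels[spl$test$labels > 0])
    expect_true(all(tr_counts == 20) && all(te_counts == 20))
  }
  s1 <- stratified_sample(sc$labels, counts = 30, seed = 42)
  s2 <- stratified_sample(sc$labels, counts = 30, seed = 42)
  expect_identical(s1$train$labels, s2$train$labels)
  expect_error(stratified_sample(sc$labels, counts = 1e6),
               "labeled pixels")
})

test_that("emulating the printed per-species test counts is possible when sized", {
  # a species with hundreds of test pixels and one with 15, as in the
  # reference sampling table, both honoured exactly
  sc <- generate_scene(scene_config(n_species = 2L, ms_rows = 40L,
                                    ms_cols = 40L, crowns_per_species = 8L,
                                    crown_radius_range = c(7, 9), seed = 12,
                                    intra_gap_prob = 0.05))
  counts <- c(`1` = 758, `2` = 15)
  # split so that the requested counts are the *test* shares
  spl <- stratified_sample(sc$labels, counts = counts, split = 0, seed = 1)
  te <- table(factor(spl$test$labels[spl$test$labels > 0], levels = 1:2))
  expect_equal(unname(te["1"]), 758L)
  expect_equal(unname(te["2"]), 15L)
})

test_that("raising the intra-canopy gap rate degrades mean test accuracy", {
  okc_at <- function(gap) {
    mean(sapply(1:4, function(s) {
      sc <- generate_scene(small_cfg(s, intra_gap_prob = gap))
      ex <- run_experiment(sc, classifiers = "mlc", schemes = 1,
                           n_train = 30, n_test = 80, seed = s + 50)
      ex$summary$okc[ex$summary$role == "test"]
    }))
  }
  okcs <- c(okc_at(0), okc_at(0.25), okc_at(0.5))
  expect_true(all(diff(okcs) < 0))
})

test_that("gaps off and large separation drive training performance to one", {
  wide_means <- rbind(c(0.05, 0.10, 0.05, 0.60),
                      c(0.10, 0.30, 0.10, 0.20),
                      c(0.30, 0.15, 0.25, 0.45),
                      c(0.08, 0.08, 0.30, 0.70),
                      c(0.20, 0.40, 0.15, 0.35))
  sc <- generate_scene(small_cfg(13, intra_gap_prob = 0,
                                 texture_amplitude = 0.02,
                                 species_means = wide_means))
  ex <- run_experiment(sc, classifiers = "mlc", schemes = 3,
                       n_train = 40, n_test = 40, seed = 77)
  tm <- ex$td_matrices$SpecTex$td
  expect_gt(min(tm[upper.tri(tm)]), 1999)
  expect_gt(ex$summary$okc[ex$summary$role == "training"], 0.99)
})
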