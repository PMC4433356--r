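aie_demo_table <- function() {
  # 4 datasets x 3 classifiers x 2 okc types, baseline minima in HMS
  grid <- expand.grid(classifier = c("mlc", "md", "sid"),
                      dataset = c("HMS", "HMS5VI", "SpecTex", "HMS13B"),
                      okc_type = c("performance", "accuracy"),
                      stringsAsFactors = FALSE)
  base <- ifelse(grid$okc_type == "performance", 0.12, 0.03)
  bump <- c(mlc = 0.5, md = 0.3, sid = 0)[grid$classifier] +
    c(HMS = 0, HMS5VI = -0.02, SpecTex = 0.3, HMS13B = 0.4)[grid$dataset]
  grid$okc <- base + pmax(bump, 0)
  grid
}

test_that("AIE worked examples reproduce the printed improvement ratios", {
  expect_equal(aie(0.98, 0.48), 0.5 / 0.48)
  expect_equal(round(100 * aie(0.98, 0.48)), 104)
  expect_equal(round(100 * aie(0.98, 0.58)), 69)
  expect_equal(aie(0.37, 0.37), 0)
  expect_error(aie(0.5, 0), "> 0")
})

test_that("AIE table picks the per-type baseline from the plain-MS scheme", {
  tab <- build_aie_table(aie_demo_table())
  mins <- attr(tab, "okc_min")
  expect_equal(unname(mins["performance"]), 0.12)   # SID / HMS cell
  expect_equal(unname(mins["accuracy"]), 0.03)
  base_rows <- tab$classifier == "sid" & tab$dataset == "HMS"
  expect_true(all(tab$aie[base_rows] == 0))
  expect_true(all(tab$aie >= 0 | tab$dataset == "HMS5VI"))
  # doubling every OKC doubles the baseline too: AIE unchanged
  d <- aie_demo_table(); d$okc <- 2 * d$okc
  expect_equal(build_aie_table(d)$aie, tab$aie, tolerance = 1e-12)
  # but doubling only non-baseline OKCs changes AIE (scale coupling)
  d2 <- aie_demo_table()
  sel <- !(d2$dataset == "HMS")
  d2$okc[sel] <- 2 * d2$okc[sel]
  expect_false(isTRUE(all.equal(build_aie_table(d2)$aie, tab$aie)))
  expect_error(build_aie_table(data.frame(classifier = "mlc",
                                          dataset = "SpecTex",
                                          okc_type = "performance",
                                          okc = 0.9)),
               "baseline dataset")
})

test_that("two-way ANOVA: null data, decomposition identity, replication", {
  null_tab <- aie_demo_table()
  null_tab$aie <- 1                   # all cells equal
  res0 <- two_way_anova(null_tab)
  expect_true(all(res0$table$f == 0))
  expect_true(all(!res0$table$significant))
  # a real table: sums of squares decompose exactly
  at <- build_aie_table(aie_demo_table())
  set.seed(30)
  at$aie <- at$aie + rnorm(nrow(at), 0, 0.05)
  res1 <- two_way_anova(at)
  ss_total <- sum((at$aie - mean(at$aie))^2)
  expect_equal(sum(res1$table$sum_sq) + res1$residual_ms * res1$residual_df,
               ss_total, tolerance = 1e-10)
  expect_equal(nrow(res1$table), 3L)   # two mains + interaction
  # unreplicated cells cannot support an interaction
  unrep <- at[at$okc_type == "performance", ]
  expect_error(two_way_anova(unrep), "replication")
  expect_s3_class(two_way_anova(unrep, interaction = FALSE), "anova_result")
})

test_that("injected dataset effects are detected; null interaction is not", {
  # one seeded table with a strong dataset main effect and no interaction
  make_tab <- function(seed, effect) {
    set.seed(seed)
    g <- expand.grid(classifier = paste0("c", 1:6),
                     dataset = paste0("d", 1:4),
                     okc_type = c("performance", "accuracy"),
                     stringsAsFactors = FALSE)
    eff <- effect * (as.integer(factor(g$dataset)) - 2.5)
    g$aie <- 1 + eff + rnorm(nrow(g), 0, 0.3)
    g
  }
  res <- two_way_anova(make_tab(1, 0.8))
  row <- function(r, term) r$table[r$table$term == term, ]
  expect_true(row(res, "dataset")$significant)
  expect_gt(row(res, "dataset")$f, row(res, "dataset:classifier")$f)
})

test_that("Duncan grouping matches the exhaustive stretch-test oracle", {
  # textbook-style five means
  means <- c(A = 9.8, B = 15.4, C = 17.6, D = 21.6, E = 10.8)
  dg <- duncan_groups(means, ms_error = 5.46, df_error = 10, n_per_mean = 4,
                      alpha = 0.05)
  share <- duncan_share_oracle(means, 5.46, 10, 4, 0.05)
  let <- dg$groups$letters
  names(let) <- dg$groups$level
  for (a in names(means)) for (b in names(means)) {
    shared <- length(intersect(strsplit(let[a], "")[[1]],
                               strsplit(let[b], "")[[1]])) > 0
    expect_equal(shared, unname(share[a, b]),
                 info = paste(a, b))
  }
  # identical means collapse to one letter
  same <- duncan_groups(c(x = 2, y = 2, z = 2), 1, 10, 4)
  expect_true(all(same$groups$letters == "a"))
  # vastly separated means get distinct letters
  far <- duncan_groups(c(x = 0, y = 100, z = 200), 1, 10, 4)
  expect_equal(anyDuplicated(far$groups$letters), 0L)
  # order consistency: letters form contiguous stretches over sorted means
  set.seed(33)
  for (i in 1:10) {
    m <- rnorm(6, 0, 1.5); names(m) <- paste0("l", 1:6)
    g <- duncan_groups(m, ms_error = 1, df_error = 12, n_per_mean = 3)
    for (ch in unique(unlist(strsplit(g$groups$letters, "")))) {
      hit <- grepl(ch, g$groups$letters)
      expect_equal(which(hit), seq(min(which(hit)), max(which(hit))))
    }
  }
  expect_error(duncan_groups(means, ms_error = -1, df_error = 10, 4), "ms_error")
})
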