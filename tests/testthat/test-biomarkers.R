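test_that("gaussianize matches the hand-evaluated single column", {
  # column (0, e-1): log1p -> (0, 1), centered (-0.5, 0.5), variance 0.5,
  # quotient (-1, 1)
  x <- matrix(c(0, exp(1) - 1), 2, 1)
  expect_equal(gaussianize(x), matrix(c(-1, 1), 2, 1))
  # z-score variant divides by the sd instead
  expect_equal(gaussianize(x, scale = "sd"),
               matrix(c(-0.5, 0.5) / sqrt(0.5), 2, 1))
  expect_error(gaussianize(matrix(0, 3, 1)), "zero-variance")
  expect_error(gaussianize(matrix(-1, 2, 1)), "non-negative")
})

test_that("normal-tagged datasets pass through gaussianize untouched", {
  ds <- expression_dataset(matrix(rnorm(12), 3), rep(c(1L, -1L), 2),
                          distribution_tag = "normal")
  expect_identical(gaussianize(ds), ds)
  # count-tagged data are transformed
  cts <- expression_dataset(matrix(rpois(12, 20), 3), rep(c(1L, -1L), 2),
                            distribution_tag = "negative_binomial")
  out <- gaussianize(cts)
  expect_equal(out$distribution_tag, "normal")
  expect_false(identical(out$values, cts$values))
})

test_that("the pooled t ranking agrees with stats::t.test per feature", {
  sp <- synthetic_spec("normal", n_majority = 12, n_minority = 8, p = 256,
                       n_informative = 10, effect_size = 1.5, seed = 21)
  ds <- generate_dataset(sp)
  rk <- rank_biomarkers(ds)
  # oracle: per-feature pooled t-test on the same true signals
  ts <- dca_transform(gaussianize(ds)$values)$true_signals
  ref_p <- apply(ts, 1, function(v) {
    stats::t.test(v[ds$labels == 1], v[ds$labels == -1],
                  var.equal = TRUE)$p.value
  })
  ord <- match(rk$ranking$feature_id, ds$feature_ids)
  expect_equal(rk$ranking$p_value, unname(ref_p[ord]), tolerance = 1e-10)
  expect_true(!is.unsorted(rk$ranking$p_value))
  expect_true(all(rk$ranking$p_value >= 0 & rk$ranking$p_value <= 1))
})

test_that("planted biomarkers surface at the top of the ranking", {
  hits <- 0L
  n_runs <- 50L
  for (seed in seq_len(n_runs)) {
    sp <- synthetic_spec("normal", n_majority = 25, n_minority = 15, p = 256,
                         n_informative = 5, effect_size = 2,
                         signal_block_len = 5L, seed = seed)
    rk <- rank_biomarkers(generate_dataset(sp))
    top10 <- rk$ranking$feature_id[1:10]
    if (all(sprintf("f%05d", 1:5) %in% top10)) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("label permutation yields null-calibrated minimum p-values", {
  # under permuted labels the per-feature tests are null; the smallest
  # p-value across p features should follow its uniform order statistic
  sp <- synthetic_spec("normal", n_majority = 15, n_minority = 15, p = 256,
                       n_informative = 0, seed = 33)
  ds <- generate_dataset(sp)
  set.seed(99)
  n_perm <- 100L
  min_p <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- ds
    perm$labels <- sample(ds$labels)
    rk <- rank_biomarkers(perm)
    min_p[i] <- rk$ranking$p_value[1]
  }
  # transform by the Beta(1, p_eff) CDF; DCA leaves ~rank(n) effective
  # dimensions so calibrate p_eff empirically via the median and test
  # uniformity shape with Kolmogorov-Smirnov at alpha = 0.01
  p_eff <- log(0.5) / log(1 - median(min_p))
  u <- 1 - (1 - min_p)^p_eff
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and no permutation produces an extreme false discovery
  expect_gt(min(min_p), 1e-8)
})

test_that("equal class means produce no spuriously tiny p-values", {
  sp <- synthetic_spec("normal", n_majority = 30, n_minority = 30, p = 256,
                       n_informative = 0, seed = 44)
  rk <- rank_biomarkers(generate_dataset(sp))
  expect_gt(min(rk$ranking$p_value), 1e-6)
})

test_that("top-k export yields linearly separable coordinates", {
  sp <- synthetic_spec("normal", n_majority = 16, n_minority = 8, p = 256,
                       n_informative = 10, effect_size = 2, seed = 55)
  ds <- generate_dataset(sp)
  rk <- rank_biomarkers(ds)
  coords <- export_top_k(rk, k = 3)
  expect_equal(dim(coords), c(24L, 5L))  # sample_id, label, 3 biomarkers
  expect_named(coords[, 1:2], c("sample_id", "label"))
  # a linear classifier on the 3 coordinates separates training perfectly
  fit <- lssvm_train(t(as.matrix(coords[, 3:5])), coords$label)
  expect_equal(predict(fit, t(as.matrix(coords[, 3:5]))), coords$label)
  # degenerate and invalid k
  expect_equal(ncol(export_top_k(rk, 0)), 2L)
  expect_error(export_top_k(rk, 500), "exceeds")
})

test_that("feature relabeling leaves the ranking order invariant", {
  sp <- synthetic_spec("normal", n_majority = 10, n_minority = 8, p = 256,
                       n_informative = 5, effect_size = 1.5, seed = 66)
  ds <- generate_dataset(sp)
  r1 <- rank_biomarkers(ds)
  ds2 <- ds
  ds2$feature_ids <- sprintf("X%05d", seq_len(256))
  rownames(ds2$values) <- ds2$feature_ids
  r2 <- rank_biomarkers(ds2)
  expect_equal(r2$ranking$p_value, r1$ranking$p_value)
  expect_equal(sub("^X", "f", r2$ranking$feature_id), r1$ranking$feature_id)
})
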