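test_that("k-fold test sets partition the index set", {
  sch <- eval_scheme("kfold", k = 5, seed = 2)
  splits <- split_indices(sch, 10)
  tests <- lapply(splits, `[[`, "test")
  expect_equal(sort(unlist(tests)), 1:10)
  expect_equal(lengths(tests), rep(2L, 5))
  for (sp in splits) {
    expect_equal(sort(c(sp$train, sp$test)), 1:10)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  expect_error(split_indices(sch, 4), "fewer samples")
})

test_that("loocv produces one singleton test per sample", {
  splits <- split_indices(eval_scheme("loocv"), 4)
  expect_length(splits, 4)
  expect_equal(sapply(splits, function(s) s$test), 1:4)
  expect_equal(lengths(lapply(splits, `[[`, "train")), rep(3L, 4))
})

test_that("monte-carlo splits are seed-deterministic with exact half sizes", {
  sch <- eval_scheme("monte_carlo", reps = 20, seed = 9)
  s1 <- split_indices(sch, 11)
  s2 <- split_indices(sch, 11)
  expect_identical(s1, s2)
  expect_true(all(sapply(s1, function(s) length(s$train)) == 6))  # ceil(11/2)
  # bernoulli mode never leaves a side empty
  schb <- eval_scheme("monte_carlo", reps = 50, split_mode = "bernoulli_half",
                      seed = 9)
  sb <- split_indices(schb, 6)
  expect_true(all(sapply(sb, function(s)
    length(s$train) >= 1 && length(s$test) >= 1)))
  expect_error(split_indices(sch, 1), "two samples")
})

test_that("stratified k-fold keeps both classes in every training fold", {
  y <- c(rep(1L, 16), rep(-1L, 4))
  splits <- split_indices(eval_scheme("kfold", k = 4, seed = 1), 20,
                          labels = y, stratify = TRUE)
  for (sp in splits) expect_length(unique(y[sp$train]), 2)
})

test_that("the rbf experiment on an amplified skewed preset shows overfitting", {
  ds <- generate_dataset(preset_spec("breastibc_like", seed = 11))
  ds <- amplify_to_min_distance(ds, 100)
  exp <- run_experiment(ds, "rbf", eval_scheme("kfold", k = 5, seed = 3))
  g <- glance(exp)
  expect_equal(g$sensitivity, 1)
  expect_equal(g$specificity, 0)
  expect_true(is.nan(g$npr))
  expect_equal(g$gram_structure, "identity_like")
  expect_equal(g$bias_type, "overfitting")
  expect_equal(abs(g$accuracy - majority_ratio(ds$labels)), 0,
               tolerance = 0.03)
})

test_that("a balanced well-separated dataset diagnoses clean under linear", {
  sp <- synthetic_spec("normal", n_majority = 25, n_minority = 25, p = 1024,
                       n_informative = 100, effect_size = 1.5, seed = 13)
  ds <- generate_dataset(sp)
  exp <- run_experiment(ds, "linear", eval_scheme("kfold", k = 5, seed = 3))
  g <- glance(exp)
  expect_gt(g$accuracy, 0.9)
  expect_equal(g$bias_type, "none")
})

test_that("experiments are byte-identical under a fixed seed", {
  ds <- generate_dataset(preset_spec("skew_1to4", seed = 4))
  sch <- eval_scheme("kfold", k = 5, seed = 17)
  e1 <- run_experiment(ds, "linear", sch, stratify = TRUE)
  e2 <- run_experiment(ds, "linear", sch, stratify = TRUE)
  expect_identical(e1$fold_metrics, e2$fold_metrics)
  expect_identical(e1$bias$bias_type, e2$bias$bias_type)
})

test_that("the positive class maps to the majority-count type by default", {
  # majority labeled -1 in the raw data; evaluation flips it to +1, so the
  # all-majority pattern scores sensitivity 1, not specificity 1
  sp <- synthetic_spec("normal", n_majority = 30, n_minority = 8, p = 1024,
                       n_informative = 0, seed = 5)
  ds <- generate_dataset(sp)
  ds <- amplify_to_min_distance(ds, 100)
  ds$labels <- -ds$labels  # majority now negative
  exp <- run_experiment(ds, "rbf", eval_scheme("kfold", k = 5, seed = 7),
                        stratify = TRUE)
  g <- glance(exp)
  expect_equal(g$sensitivity, 1)
  expect_equal(g$specificity, 0)
})

test_that("single-class training folds raise a descriptive error", {
  sp <- synthetic_spec("normal", n_majority = 9, n_minority = 1, p = 256,
                       seed = 2)
  ds <- generate_dataset(sp)
  # loocv on 10 samples: the fold dropping the lone minority sample is fine,
  # but k-fold with k = 2 and stratify off can isolate it; force the error
  # with a direct check instead of relying on chance
  expect_error(
    run_experiment(select_samples(ds, c(10, 1, 2)), "linear",
                   eval_scheme("loocv")),
    "single class")
})
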