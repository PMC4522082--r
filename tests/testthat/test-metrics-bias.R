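test_that("confusion metrics reproduce the all-positive skewed pattern", {
  # 475 positives, 68 negatives, everything predicted positive
  y_true <- c(rep(1L, 475), rep(-1L, 68))
  y_pred <- rep(1L, 543)
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(round(m$accuracy, 4), 0.8748)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_true(is.nan(m$npr))
  expect_equal(round(m$ppr, 4), 0.8748)
})

test_that("confusion metrics follow the printed formulas", {
  perfect <- confusion_metrics(c(1, -1, 1), c(1, -1, 1))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                "ppr", "npr")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 ppr = 1, npr = 1))
  # tp=3 fp=1 tn=2 fn=2
  y_true <- c(1, 1, 1, 1, 1, -1, -1, -1)
  y_pred <- c(1, 1, 1, -1, -1, 1, -1, -1)
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 2 / 3)
  expect_equal(m$ppr, 0.75)
  expect_equal(m$npr, 0.5)
  expect_error(confusion_metrics(integer(0), integer(0)), "empty")
})

test_that("all-majority prediction forces sens 1 / spec 0 identically", {
  for (n_min in c(1, 5, 20)) {
    y_true <- c(rep(1L, 30), rep(-1L, n_min))
    m <- confusion_metrics(y_true, rep(1L, 30 + n_min))
    expect_equal(m$sensitivity, 1)
    expect_equal(m$specificity, 0)
    expect_true(is.nan(m$npr))
    expect_equal(m$accuracy, majority_ratio(y_true))
  }
})

test_that("diagnostic index reproduces published worked values", {
  expect_equal(diagnostic_index(1, 1, 1), 0)
  expect_equal(round(diagnostic_index(0.9668, 1, 0), 4), 1.0487)
  expect_equal(round(diagnostic_index(0.9663, 1, 0), 4), 1.0495)
  expect_equal(round(diagnostic_index(0.9952, 0.9964, 0.97), 4), 0.0314)
  expect_equal(round(diagnostic_index(0.5628, 0.5673, 0.4377), 4), 1.8221)
  expect_equal(diagnostic_index(0.9, 0, 0), Inf)
  expect_error(diagnostic_index(0, 1, 1), "positive")
})

test_that("diagnostic index decreases in each argument", {
  base <- diagnostic_index(0.8, 0.8, 0.6)
  expect_lt(diagnostic_index(0.9, 0.8, 0.6), base)
  expect_lt(diagnostic_index(0.8, 0.9, 0.6), base)
  expect_lt(diagnostic_index(0.8, 0.8, 0.7), base)
})

test_that("majority ratios match the benchmark label distributions", {
  expect_equal(round(majority_ratio(c(rep(1, 34), rep(-1, 13))), 4), 0.7234)
  expect_equal(majority_ratio(c(rep(1, 5), rep(-1, 5))), 0.5)
  expect_equal(round(majority_ratio(c(rep(1, 516), rep(-1, 18))), 4), 0.9663)
  expect_equal(majority_ratio(c(rep(-1, 475), rep(1, 68))), 475 / 543)
})

test_that("bias rules classify the published benchmark patterns", {
  th <- bias_thresholds()
  kidney <- label_counts(c(rep(1L, 475), rep(-1L, 68)))
  over <- classify_bias(list(accuracy = 0.8748, sensitivity = 1,
                             specificity = 0),
                        kidney, "identity_like", thresholds = th)
  expect_equal(over$bias_type, "overfitting")
  implicit <- classify_bias(list(accuracy = 0.9023, sensitivity = 0.9684,
                                 specificity = 0.4407),
                            kidney, "normal", thresholds = th)
  expect_equal(implicit$bias_type, "implicit_label_skew")
  under <- classify_bias(list(accuracy = 0.5339, sensitivity = 0.5432,
                              specificity = 0.4692),
                         kidney, "flat_like", thresholds = th)
  expect_equal(under$bias_type, "underfitting")
  hcc <- label_counts(c(rep(1L, 78), rep(-1L, 72)))
  none <- classify_bias(list(accuracy = 0.9402, sensitivity = 0.9581,
                             specificity = 0.9242),
                        hcc, "normal", thresholds = th)
  expect_equal(none$bias_type, "none")
  # explicit skew: accuracy pinned at the ratio with a wide sens/spec gap
  breast <- label_counts(c(rep(1L, 34), rep(-1L, 13)))
  expl <- classify_bias(list(accuracy = 0.7456, sensitivity = 0.9714,
                             specificity = 0.1667),
                        breast, "normal", thresholds = th)
  expect_equal(expl$bias_type, "explicit_label_skew")
})

test_that("aggregation averages folds and propagates NaN", {
  f1 <- confusion_metrics(c(1, 1, -1, -1), c(1, -1, 1, -1))
  f2 <- confusion_metrics(c(1, 1, -1, -1), c(1, 1, 1, 1))  # NaN npr
  agg <- aggregate_metrics(dplyr::bind_rows(f1, f2))
  expect_true(is.nan(agg$mean[agg$metric == "npr"]))
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(acc$mean, mean(c(0.5, 0.5)))
  # identical folds have zero spread; a 0.7/0.9 pair gives 0.8 +/- 0.1414
  same <- aggregate_metrics(dplyr::bind_rows(f1, f1))
  expect_equal(same$sd[same$metric == "accuracy"], 0)
  two <- dplyr::bind_rows(
    dplyr::mutate(f1, accuracy = 0.7), dplyr::mutate(f1, accuracy = 0.9))
  agg2 <- aggregate_metrics(two)
  expect_equal(agg2$mean[agg2$metric == "accuracy"], 0.8)
  expect_equal(round(agg2$sd[agg2$metric == "accuracy"], 4), 0.1414)
})

test_that("percent formatting renders the table layout", {
  agg <- tibble::tibble(metric = c("accuracy", "npr"),
                        mean = c(0.8748, NaN), sd = c(0.0044, NaN))
  fmt <- format_metrics_percent(agg)
  expect_equal(fmt$formatted[1], "87.48 ± 00.44")
  expect_equal(fmt$formatted[2], "NaN ± NaN")
})
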