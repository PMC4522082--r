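#' Confusion-matrix diagnostics with NaN semantics
#'
#' Computes the five diagnostic measures from true and predicted labels, with
#' `+1` the positive class: accuracy `(TP+TN)/total`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive ratio
#' `TP/(TP+FP)` and negative predictive ratio `TN/(TN+FN)`. A `0/0` ratio is
#' `NaN`, not an error: when a biased classifier predicts every sample
#' positive, `TN = FN = 0` and the NPR is NaN while sensitivity is exactly 1
#' and specificity exactly 0. The diagnostic index `beta` is attached when
#' computable (NaN inputs propagate).
#'
#' @param y_true,y_pred Equal-length label vectors in \{-1, +1\}.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `ppr`, `npr`, `beta`.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (!all(c(y_true, y_pred) %in% c(-1L, 1L))) stop("labels must be -1 or +1")
  tp <- sum(y_true == 1L & y_pred == 1L)
  tn <- sum(y_true == -1L & y_pred == -1L)
  fp <- sum(y_true == -1L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == -1L)
  acc <- (tp + tn) / length(y_true)
  sens <- ratio_or_nan(tp, tp + fn)
  spec <- ratio_or_nan(tn, tn + fp)
  ppr <- ratio_or_nan(tp, tp + fp)
  npr <- ratio_or_nan(tn, tn + fn)
  beta <- if (is.nan(sens) || is.nan(spec) || acc <= 0) {
    NaN
  } else {
    diagnostic_index(acc, sens, spec)
  }
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn, accuracy = acc,
                 sensitivity = sens, specificity = spec, ppr = ppr,
                 npr = npr, beta = beta)
}

ratio_or_nan <- function(num, den) if (den == 0L) NaN else num / den

#' Diagnostic index
#'
#' `beta = -log2(a) - log2((s + p) / 2)` with `a` accuracy, `s` sensitivity,
#' `p` specificity. Zero means a perfect diagnosis; values around 1 flag a
#' classifier whose accuracy is carried by the majority class (`s + p`
#' averaging 1/2); values around 2 flag near-random diagnosis. `s + p = 0`
#' yields `+Inf`.
#'
#' @param accuracy Accuracy in (0, 1].
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @return The index value (report it rounded to 4 decimals in tables).
#' @export
diagnostic_index <- function(accuracy, sensitivity, specificity) {
  if (any(accuracy <= 0)) stop("accuracy must be positive")
  sp <- (sensitivity + specificity) / 2
  ifelse(sp == 0, Inf, -log2(accuracy) - log2(sp))
}

#' Majority-count ratio
#'
#' Fraction of samples in the more numerous class: the deceptive accuracy
#' floor that overfitting- and skew-biased classifiers collapse to.
#'
#' @param counts A [label_counts()] object, or a label vector.
#' @return Fraction in \[1/2, 1\].
#' @export
majority_ratio <- function(counts) {
  if (!inherits(counts, "label_counts")) counts <- label_counts(counts)
  total <- counts$n_positive + counts$n_negative
  if (total == 0L) stop("empty label set")
  counts$majority_count / total
}

#' Aggregate per-fold metrics
#'
#' Mean and standard deviation of each metric over evaluation folds. NaN
#' values propagate: if any fold's NPR is NaN (no sample predicted negative
#' in that fold), the aggregated NPR is NaN, matching how biased runs are
#' reported.
#'
#' @param fold_metrics A tibble of per-fold rows from [confusion_metrics()]
#'   (or a list of such rows).
#' @return A tibble with one row per metric: `metric`, `mean`, `sd`.
#' @export
aggregate_metrics <- function(fold_metrics) {
  if (is.list(fold_metrics) && !is.data.frame(fold_metrics)) {
    fold_metrics <- dplyr::bind_rows(fold_metrics)
  }
  if (nrow(fold_metrics) == 0L) stop("no folds to aggregate")
  cols <- c("accuracy", "sensitivity", "specificity", "npr", "ppr", "beta")
  cols <- intersect(cols, names(fold_metrics))
  purrr::map_dfr(cols, function(cl) {
    v <- fold_metrics[[cl]]
    tibble::tibble(
      metric = cl,
      mean = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else 0
    )
  })
}

#' Format an aggregated metric table as percentages
#'
#' Renders "mean ± sd" strings in percent with two decimals, the layout used
#' for diagnostic benchmark tables. NaN prints as "NaN".
#'
#' @param agg Output of [aggregate_metrics()].
#' @return A tibble with `metric` and `formatted` columns.
#' @export
format_metrics_percent <- function(agg) {
  fmt1 <- function(v) {
    ifelse(!is.finite(v), "NaN", sprintf("%05.2f", 100 * v))
  }
  keep <- agg$metric != "beta"
  tibble::tibble(
    metric = agg$metric[keep],
    formatted = paste0(fmt1(agg$mean[keep]), " ± ", fmt1(agg$sd[keep]))
  )
}
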