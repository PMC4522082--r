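#' Evaluation scheme
#'
#' Defines how train/test splits are drawn: `kfold` (disjoint near-equal
#' folds), `loocv` (one singleton test set per sample), or `monte_carlo`
#' (repeated independent half splits — `fixed_half` draws exactly
#' `ceiling(n/2)` training samples per repetition; `bernoulli_half` gives
#' each sample an independent fair coin, redrawing repetitions that leave
#' either side empty). All randomness flows from `seed`.
#'
#' @param kind `"kfold"`, `"loocv"`, or `"monte_carlo"`.
#' @param k Number of folds (kfold; default 5).
#' @param reps Repetitions (monte_carlo; default 500).
#' @param train_fraction Training fraction for monte_carlo (0.5).
#' @param split_mode `"fixed_half"` or `"bernoulli_half"` (monte_carlo).
#' @param seed Integer seed controlling all splits.
#' @return An `eval_scheme` object.
#' @export
eval_scheme <- function(kind = c("kfold", "loocv", "monte_carlo"),
                        k = 5L, reps = 500L, train_fraction = 0.5,
                        split_mode = c("fixed_half", "bernoulli_half"),
                        seed = 1L) {
  kind <- match.arg(kind)
  split_mode <- match.arg(split_mode)
  k <- as.integer(k)
  reps <- as.integer(reps)
  if (kind == "kfold" && k < 2L) stop("k must be >= 2")
  if (kind == "monte_carlo" && reps < 1L) stop("reps must be >= 1")
  structure(list(kind = kind, k = k, reps = reps,
                 train_fraction = train_fraction, split_mode = split_mode,
                 seed = as.integer(seed)),
            class = "eval_scheme")
}

#' @export
print.eval_scheme <- function(x, ...) {
  desc <- switch(x$kind,
    kfold = paste0(x$k, "-fold CV"),
    loocv = "leave-one-out CV",
    monte_carlo = paste0(x$reps, " Monte-Carlo ", x$split_mode, " splits"))
  cat("<eval_scheme> ", desc, " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Draw train/test index splits
#'
#' @param scheme An [eval_scheme()].
#' @param n Number of samples.
#' @param labels Optional labels; when given with `stratify = TRUE`, k-fold
#'   partitions are drawn within each class so that every fold carries both
#'   phenotypes.
#' @param stratify Stratify the k-fold partition by class (default FALSE,
#'   plain random partition).
#' @return A list of `list(train, test)` integer index pairs. k-fold test
#'   sets are disjoint and exhaust `1:n`.
#' @export
split_indices <- function(scheme, n, labels = NULL, stratify = FALSE) {
  stopifnot(inherits(scheme, "eval_scheme"))
  n <- as.integer(n)
  if (n < 2L) stop("need at least two samples to split")
  with_seed(scheme$seed, {
    switch(scheme$kind,
      loocv = lapply(seq_len(n), function(i) {
        list(train = setdiff(seq_len(n), i), test = i)
      }),
      kfold = {
        k <- scheme$k
        if (n < k) stop("fewer samples than folds")
        fold <- if (stratify && !is.null(labels)) {
          f <- integer(n)
          for (cl in unique(labels)) {
            idx <- which(labels == cl)
            f[sample(idx)] <- rep_len(seq_len(k), length(idx))
          }
          f
        } else {
          f <- integer(n)
          f[sample.int(n)] <- rep_len(seq_len(k), n)
          f
        }
        lapply(seq_len(k), function(i) {
          list(train = which(fold != i), test = which(fold == i))
        })
      },
      monte_carlo = {
        lapply(seq_len(scheme$reps), function(r) {
          if (scheme$split_mode == "fixed_half") {
            n_tr <- ceiling(n * scheme$train_fraction)
            tr <- sort(sample.int(n, n_tr))
          } else {
            repeat {
              sel <- stats::runif(n) < scheme$train_fraction
              if (any(sel) && any(!sel)) break
            }
            tr <- which(sel)
          }
          list(train = tr, test = setdiff(seq_len(n), tr))
        })
      }
    )
  })
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Run a full diagnostic experiment
#'
#' Ties the pipeline together: for every split of the scheme, standardize the
#' training samples (the per-sample scaling is fit-free, so test samples are
#' scaled by the same rule), fit the classifier, predict the held-out
#' samples, and score them; then aggregate the per-fold metrics, attach the
#' Gram structure of the full training Gram and the per-fold signed
#' multiplier summaries, and classify the diagnostic bias.
#'
#' By default the positive class is remapped to the majority-count type
#' before evaluation, the convention under which the biased runs show
#' sensitivity 1 / specificity 0.
#'
#' @param x An `expression_dataset`.
#' @param classifier `"linear"`, `"rbf"`, `"rbf2"`, `"quad"`, `"mlp"`
#'   (LS-SVM kernels) or `"dca_svm"`.
#' @param scheme An [eval_scheme()].
#' @param C LS-SVM penalty (default 1).
#' @param params [dca_params()] for the `dca_svm` classifier.
#' @param thresholds [bias_thresholds()] for the bias rules.
#' @param positive `"majority"` (default: remap so the majority class is
#'   `+1`) or `"label"` (keep the dataset's labels).
#' @param stratify Stratify k-fold splits by class (default FALSE).
#' @param transform_mode Passed to [dca_svm()].
#' @return A `bias_experiment`: `fold_metrics` (tibble, one row per fold),
#'   `summary` (mean ± sd per metric), `bias` (a `bias_report`),
#'   `gram_structure`, `alpha_reports`, plus the effective configuration.
#' @export
run_experiment <- function(x, classifier = c("linear", "rbf", "rbf2", "quad",
                                             "mlp", "dca_svm"),
                           scheme = eval_scheme("kfold"), C = 1,
                           params = dca_params(),
                           thresholds = bias_thresholds(),
                           positive = c("majority", "label"),
                           stratify = FALSE,
                           transform_mode = c("joint", "inductive")) {
  classifier <- match.arg(classifier)
  positive <- match.arg(positive)
  transform_mode <- match.arg(transform_mode)
  stopifnot(inherits(x, "expression_dataset"))
  y <- x$labels
  if (positive == "majority") {
    counts <- label_counts(y)
    if (counts$majority_label == -1L) y <- -y
  }
  counts <- label_counts(y)
  n <- length(y)
  splits <- split_indices(scheme, n, labels = y, stratify = stratify)
  xs_full <- standardize_samples(x$values)
  full_spec <- classifier_kernel_spec(classifier, xs_full)
  full_gram <- gram_matrix(full_spec,
                           if (classifier == "dca_svm")
                             dca_transform(xs_full, params)$true_signals
                           else xs_full)
  fold_rows <- vector("list", length(splits))
  alpha_reports <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    y_tr <- y[sp$train]
    if (length(unique(y_tr)) < 2L) {
      stop("training fold ", i, " contains a single class; ",
           "use stratify = TRUE or a different seed")
    }
    x_tr <- standardize_samples(x$values[, sp$train, drop = FALSE])
    x_te <- standardize_samples(x$values[, sp$test, drop = FALSE])
    res <- tryCatch({
      if (classifier == "dca_svm") {
        model <- dca_svm(x$values[, sp$train, drop = FALSE], y_tr,
                         params = params, C = C,
                         transform_mode = transform_mode)
        pred <- predict(model, x$values[, sp$test, drop = FALSE])
        list(pred = pred, lssvm = model$lssvm)
      } else {
        spec <- classifier_kernel_spec(classifier, x_tr)
        model <- lssvm_train(x_tr, y_tr, spec = spec, C = C)
        list(pred = predict(model, x_te), lssvm = model)
      }
    }, error = function(e) {
      stop("classifier failed on fold ", i, ": ", conditionMessage(e))
    })
    fold_rows[[i]] <- dplyr::mutate(confusion_metrics(y[sp$test], res$pred),
                                    fold = i, .before = 1L)
    alpha_reports[[i]] <- signed_alpha_report(res$lssvm)
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  summary <- aggregate_metrics(fold_metrics)
  mean_of <- function(metric) summary$mean[summary$metric == metric]
  bias <- classify_bias(
    list(accuracy = mean_of("accuracy"), sensitivity = mean_of("sensitivity"),
         specificity = mean_of("specificity")),
    counts, full_gram$structure,
    alpha_report = alpha_reports[[1L]], thresholds = thresholds)
  structure(
    list(fold_metrics = fold_metrics, summary = summary, bias = bias,
         gram_structure = full_gram$structure,
         alpha_reports = alpha_reports, counts = counts,
         classifier = classifier, scheme = scheme, C = C,
         params = if (classifier == "dca_svm") params else NULL,
         positive = positive,
         transform_mode = if (classifier == "dca_svm") transform_mode else NULL),
    class = "bias_experiment"
  )
}

classifier_kernel_spec <- function(classifier, x_std) {
  switch(classifier,
    dca_svm = kernel_spec("linear"),
    rbf2 = kernel_spec("rbf2", bandwidth_sq = rbf2_bandwidth(x_std)),
    kernel_spec(classifier))
}

#' @export
print.bias_experiment <- function(x, ...) {
  cat("<bias_experiment> ", x$classifier, " under ", sep = "")
  print(x$scheme)
  fmt <- format_metrics_percent(x$summary)
  for (i in seq_len(nrow(fmt))) {
    cat(sprintf("  %-12s %s\n", fmt$metric[i], fmt$formatted[i]))
  }
  print(x$bias)
  invisible(x)
}

#' Tidy a bias experiment
#'
#' @param x A `bias_experiment`.
#' @param ... Unused.
#' @return The per-fold metric tibble.
#' @method tidy bias_experiment
#' @export
tidy.bias_experiment <- function(x, ...) x$fold_metrics

#' One-row summary of a bias experiment
#'
#' @param x A `bias_experiment`.
#' @param ... Unused.
#' @return A one-row tibble with the mean metrics, the Gram structure and
#'   the classified bias type.
#' @method glance bias_experiment
#' @export
glance.bias_experiment <- function(x, ...) {
  s <- x$summary
  out <- tibble::as_tibble(as.list(stats::setNames(s$mean, s$metric)))
  out$gram_structure <- x$gram_structure
  out$bias_type <- x$bias$bias_type
  out$classifier <- x$classifier
  out$n_folds <- nrow(x$fold_metrics)
  out
}

#' Per-fold metric plot for a bias experiment
#'
#' @param object A `bias_experiment`.
#' @param ... Unused.
#' @return A ggplot object showing per-fold accuracy, sensitivity and
#'   specificity.
#' @method autoplot bias_experiment
#' @export
autoplot.bias_experiment <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$fold_metrics[, c("fold", "accuracy", "sensitivity", "specificity")],
    -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = paste0(object$classifier, ": per-fold metrics (bias: ",
                                 object$bias$bias_type, ")"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
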