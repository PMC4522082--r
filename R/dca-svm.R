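#' Fit the DCA-SVM classifier
#'
#' The composed classifier that conquers label-skewness bias: samples are
#' standardized, DCA extracts their true signals, and a linear-kernel LS-SVM
#' is trained on the true signals. The low-rank per-level reconstruction
#' strips most per-sample noise, so the hyperplane is driven by the shared
#' class structure rather than by the skew of the label counts.
#'
#' @param x Training data: an `expression_dataset` (labels taken from it) or
#'   a features-x-samples matrix with `y` supplied. Both classes must be
#'   present.
#' @param y Labels in \{-1, +1\} when `x` is a matrix.
#' @param params [dca_params()] controlling the true-signal extraction.
#' @param C LS-SVM penalty (default 1).
#' @param kernel Kernel family for the LS-SVM stage; linear by default.
#' @param transform_mode How unseen samples are transformed at prediction:
#'   `"joint"` (default) re-runs DCA on the stored training matrix with the
#'   test columns appended — a transductive step that shares unlabeled test
#'   structure with the fitted bases and is flagged in reports; or
#'   `"inductive"`, which freezes the per-level principal-component bases
#'   from training and projects test coefficients onto them.
#' @return An object of class `dca_svm`.
#' @export
dca_svm <- function(x, y = NULL, params = dca_params(), C = 1,
                    kernel = "linear",
                    transform_mode = c("joint", "inductive")) {
  transform_mode <- match.arg(transform_mode)
  if (inherits(x, "expression_dataset")) {
    if (is.null(y)) y <- x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("single-class training set: both phenotypes must be present")
  }
  xs <- standardize_samples(x)
  dres <- dca_transform(xs, params, keep_bases = (transform_mode == "inductive"))
  model <- lssvm_train(dres$true_signals, y, spec = kernel_spec(kernel), C = C)
  structure(
    list(dca_params = params, lssvm = model,
         train_true_signals = dres$true_signals,
         train_standardized = xs, per_level_rank = dres$per_level_rank,
         bases = dres$bases, transform_mode = transform_mode),
    class = "dca_svm"
  )
}

#' Decision values of a DCA-SVM on new samples
#'
#' New samples are standardized by the same per-sample rule, converted to
#' true signals by the model's transform mode, and pushed through the LS-SVM
#' decision rule against the stored training true signals.
#'
#' @param model A fitted `dca_svm`.
#' @param x_new New samples (matrix or `expression_dataset`).
#' @return Numeric decision values.
#' @export
dca_decision_values <- function(model, x_new) {
  stopifnot(inherits(model, "dca_svm"))
  mat <- if (inherits(x_new, "expression_dataset")) x_new$values else as.matrix(x_new)
  if (ncol(mat) == 0L) return(numeric(0))
  if (nrow(mat) != nrow(model$train_standardized)) stop("feature mismatch")
  ms <- standardize_samples(mat)
  y_new <- if (model$transform_mode == "joint") {
    joint <- cbind(model$train_standardized, ms)
    dres <- dca_transform(joint, model$dca_params)
    n_tr <- ncol(model$train_standardized)
    dres$true_signals[, n_tr + seq_len(ncol(ms)), drop = FALSE]
  } else {
    dca_project(ms, model$dca_params, model$bases)
  }
  decision_values(model$lssvm, y_new)
}

#' Predict phenotype labels with a DCA-SVM
#'
#' @param object A fitted `dca_svm`.
#' @param x_new New samples.
#' @param ... Unused.
#' @return Integer labels in \{-1, +1\} (sign of the decision value; zero
#'   maps to +1).
#' @export
predict.dca_svm <- function(object, x_new, ...) {
  d <- dca_decision_values(object, x_new)
  ifelse(d >= 0, 1L, -1L)
}

#' @export
print.dca_svm <- function(x, ...) {
  cat("<dca_svm> ", ncol(x$train_true_signals), " training samples, ",
      x$lssvm$spec$family, " kernel on true signals, transform mode: ",
      x$transform_mode, "\n", sep = "")
  print(x$dca_params)
  invisible(x)
}

#' @method tidy dca_svm
#' @export
tidy.dca_svm <- function(x, ...) tidy(x$lssvm, ...)

#' @method glance dca_svm
#' @export
glance.dca_svm <- function(x, ...) {
  out <- glance(x$lssvm, ...)
  out$transform_mode <- x$transform_mode
  out
}
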