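#' Train a least-squares SVM
#'
#' The LS-SVM replaces the C-SVM's inequality constraints with equalities, so
#' the dual reduces to one linear system: with ridge `mu = 1/C` on the Gram
#' diagonal,
#' \deqn{\begin{bmatrix} 0 & 1^T \\ 1 & K + I/C \end{bmatrix}
#'       \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ y \end{bmatrix}.}
#' The first row enforces `sum(alpha) = 0`; the remaining rows are the
#' stationarity conditions. The solution is dense: every training sample
#' carries a (possibly tiny) multiplier, and "support vectors" in reports are
#' all samples with `|alpha_i| > 1e-12`.
#'
#' @param x Standardized training samples, features x samples (matrix or
#'   `expression_dataset`). Standardize with [standardize_samples()] first;
#'   the same fit-free scaling applies to test samples.
#' @param y Labels in \{-1, +1\} (taken from `x` when it is an
#'   `expression_dataset` and `y` is missing).
#' @param spec A [kernel_spec()]; an `rbf2` spec with unset bandwidth is tuned
#'   on the training samples and the tuned value is frozen into the model.
#' @param C Positive penalty parameter; 1 throughout, chosen generically
#'   rather than per-dataset so that multiplier values stay comparable across
#'   balanced and skewed datasets.
#' @param K Optional precomputed `gram_matrix` for `x` (avoids recomputation).
#' @return An object of class `lssvm` with elements `alphas`, `bias`,
#'   `train_x`, `train_y`, `spec`, `penalty`, `ridge`, `gram_structure`.
#' @export
lssvm_train <- function(x, y = NULL, spec = kernel_spec("linear"), C = 1,
                        K = NULL) {
  if (inherits(x, "expression_dataset")) {
    if (is.null(y)) y <- x$labels
    x <- x$values
  }
  x <- as.matrix(x)
  y <- as.numeric(y)
  m <- ncol(x)
  if (length(y) != m) stop("labels length must equal the number of samples")
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  if (C <= 0) stop("penalty C must be positive")
  if (is.null(K)) K <- gram_matrix(spec, x)
  stopifnot(inherits(K, "gram_matrix"), nrow(K$values) == m)
  sol <- lssvm_solve(K$values, y, C)
  structure(
    list(alphas = sol$alpha, bias = sol$b, train_x = x, train_y = y,
         spec = K$spec, penalty = C, ridge = 1 / C,
         gram_structure = K$structure),
    class = "lssvm"
  )
}

#' Solve the LS-SVM dual linear system
#'
#' Low-level solver used by [lssvm_train()]; exposed so the bordered system
#' can be exercised directly on an arbitrary kernel matrix. Falls back to a
#' pseudoinverse least-squares solution with a warning if the bordered system
#' is singular or numerically unsolvable (which the non-PSD `mlp` kernel can
#' produce).
#'
#' @param Kmat Square m x m kernel matrix (plain numeric matrix).
#' @param y Labels in \{-1, +1\}, length m.
#' @param C Positive penalty.
#' @return List with `alpha` (length m) and `b`.
#' @export
lssvm_solve <- function(Kmat, y, C = 1) {
  m <- length(y)
  stopifnot(nrow(Kmat) == m, ncol(Kmat) == m)
  A <- rbind(c(0, rep(1, m)), cbind(1, Kmat + diag(m) / C))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    warning("LS-SVM system is singular or ill-conditioned; ",
            "using a least-squares pseudoinverse solution")
    sol <- drop(MASS::ginv(A) %*% rhs)
  }
  list(b = sol[1L], alpha = sol[-1L])
}

#' Decision values of an LS-SVM on new samples
#'
#' `f(x') = sum_i alpha_i k(x_i, x') + b`, before taking the sign.
#'
#' @param model A fitted `lssvm`.
#' @param x_new New samples, features x samples (standardized by the same
#'   per-sample rule as training), or an `expression_dataset`.
#' @return Numeric vector of decision values (length = number of new samples;
#'   empty input gives an empty vector).
#' @export
decision_values <- function(model, x_new) {
  stopifnot(inherits(model, "lssvm"))
  mat <- if (inherits(x_new, "expression_dataset")) x_new$values else as.matrix(x_new)
  if (ncol(mat) == 0L) return(numeric(0))
  if (nrow(mat) != nrow(model$train_x)) stop("feature-length mismatch")
  Kc <- gram_matrix(model$spec, model$train_x, x2 = mat)  # new x train
  drop(Kc %*% model$alphas) + model$bias
}

#' Predict class labels with an LS-SVM
#'
#' Sign of the decision value; an exact zero maps to `+1` (deterministic tie
#' rule, consistent with the majority class being labeled `+1`).
#'
#' @param object A fitted `lssvm`.
#' @param x_new New samples (see [decision_values()]).
#' @param ... Unused.
#' @return Integer vector of labels in \{-1, +1\}.
#' @export
predict.lssvm <- function(object, x_new, ...) {
  d <- decision_values(object, x_new)
  ifelse(d >= 0, 1L, -1L)
}

#' Signed support-vector weight report
#'
#' LS-SVM multipliers are reported as `|alpha_i|` carrying the class sign of
#' sample `i`, so a positive (negative) sign marks a weight attached to a
#' positive (negative) training sample. Under skewed labels the positive-sign
#' weights outnumber the negative-sign ones and the intercept is positive:
#' the signature of label-skewness bias.
#'
#' @param model A fitted `lssvm`.
#' @param tol Multipliers with `|alpha_i| <= tol` are not counted as support
#'   vectors.
#' @return List with `signed_alphas`, `n_positive_sign`, `n_negative_sign`,
#'   `bias_sign` (class `signed_alpha_report`).
#' @export
signed_alpha_report <- function(model, tol = 1e-12) {
  stopifnot(inherits(model, "lssvm"))
  signed <- abs(model$alphas) * model$train_y
  nz <- abs(model$alphas) > tol
  structure(
    list(signed_alphas = signed,
         n_positive_sign = sum(nz & model$train_y > 0),
         n_negative_sign = sum(nz & model$train_y < 0),
         bias_sign = sign(model$bias)),
    class = "signed_alpha_report"
  )
}

#' @export
print.signed_alpha_report <- function(x, ...) {
  cat("<signed_alpha_report> ", x$n_positive_sign, " positive-sign / ",
      x$n_negative_sign, " negative-sign weights; b sign ",
      c("-", "0", "+")[x$bias_sign + 2], "\n", sep = "")
  invisible(x)
}

#' @export
print.lssvm <- function(x, ...) {
  cat("<lssvm> ", length(x$alphas), " training samples, ", x$spec$family,
      " kernel, C = ", x$penalty, "\n", sep = "")
  cat("  b = ", format(x$bias, digits = 6), ", sum(alpha) = ",
      format(sum(x$alphas), digits = 3), ", gram: ", x$gram_structure,
      "\n", sep = "")
  invisible(x)
}

#' Tidy an LS-SVM model
#'
#' One row per training sample with its multiplier and signed weight.
#'
#' @param x A fitted `lssvm`.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `label`, `alpha`, `signed_alpha`.
#' @method tidy lssvm
#' @export
tidy.lssvm <- function(x, ...) {
  tibble::tibble(
    sample = colnames(x$train_x) %||% seq_along(x$alphas),
    label = as.integer(x$train_y),
    alpha = x$alphas,
    signed_alpha = abs(x$alphas) * x$train_y
  )
}

#' One-row model summary of an LS-SVM
#'
#' @param x A fitted `lssvm`.
#' @param ... Unused.
#' @return A one-row tibble: kernel family, penalty, intercept, multiplier
#'   sign counts and Gram structure.
#' @method glance lssvm
#' @export
glance.lssvm <- function(x, ...) {
  rep <- signed_alpha_report(x)
  tibble::tibble(
    kernel = x$spec$family,
    penalty = x$penalty,
    bias = x$bias,
    n_positive_sign = rep$n_positive_sign,
    n_negative_sign = rep$n_negative_sign,
    gram_structure = x$gram_structure
  )
}

#' Serialize an LS-SVM model to structured text
#'
#' Writes multipliers, intercept, kernel spec and training sample ids as a
#' plain-text R expression readable with [read_lssvm()]. The training matrix
#' itself is included so the model file is self-contained.
#'
#' @param model A fitted `lssvm`.
#' @param path Output path.
#' @return `model`, invisibly.
#' @export
write_lssvm <- function(model, path) {
  stopifnot(inherits(model, "lssvm"))
  plain <- unclass(model)
  dput(plain, file = path, control = c("keepNA", "keepInteger", "showAttributes"))
  invisible(model)
}

#' @rdname write_lssvm
#' @export
read_lssvm <- function(path) {
  obj <- dget(path)
  class(obj$spec) <- "kernel_spec"
  structure(obj, class = "lssvm")
}
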