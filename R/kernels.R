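#' Kernel specification
#'
#' The five kernel families used for diagnosis. The Gaussian `rbf` kernel is
#' `exp(-||x - x'||^2 / (2 sigma^2))` with `sigma^2 = 1` by default; `rbf2` is
#' the same form with the bandwidth tuned to the total variation of the
#' training samples (see [rbf2_bandwidth()]). `quad` is `(1 + x.x')^2`, `mlp`
#' is `tanh(x.x' - 1)` (not positive semidefinite; it is included because it
#' induces the underfitting bias), and `linear` is the plain inner product.
#'
#' @param family One of `"linear"`, `"rbf"`, `"rbf2"`, `"quad"`, `"mlp"`.
#' @param bandwidth_sq Positive bandwidth `sigma^2`; only meaningful for the
#'   `rbf`/`rbf2` families. Defaults to 1 for `rbf`; for `rbf2` it is normally
#'   filled in from the training data at fit time.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("linear", "rbf", "rbf2", "quad", "mlp"),
                        bandwidth_sq = NULL) {
  family <- match.arg(family)
  if (family %in% c("rbf", "rbf2")) {
    if (is.null(bandwidth_sq)) bandwidth_sq <- if (family == "rbf") 1 else NA_real_
    if (!is.na(bandwidth_sq) && bandwidth_sq <= 0) stop("bandwidth_sq must be positive")
  } else {
    if (!is.null(bandwidth_sq)) stop("bandwidth_sq applies only to rbf/rbf2 kernels")
    bandwidth_sq <- NA_real_
  }
  structure(list(family = family, bandwidth_sq = bandwidth_sq),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  bw <- if (is.na(x$bandwidth_sq)) "" else sprintf(" (sigma^2 = %g)", x$bandwidth_sq)
  cat("<kernel_spec> ", x$family, bw, "\n", sep = "")
  invisible(x)
}

#' Evaluate a kernel on a pair of sample vectors
#'
#' @param spec A [kernel_spec()].
#' @param x,x2 Numeric vectors of equal length.
#' @return The scalar kernel value.
#' @export
kernel_value <- function(spec, x, x2) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(x2)) stop("vector length mismatch")
  switch(spec$family,
    linear = sum(x * x2),
    quad = (1 + sum(x * x2))^2,
    mlp = tanh(sum(x * x2) - 1),
    rbf = ,
    rbf2 = {
      s2 <- spec$bandwidth_sq
      if (is.na(s2)) stop("rbf2 bandwidth not set; compute it with rbf2_bandwidth()")
      exp(-sum((x - x2)^2) / (2 * s2))
    }
  )
}

#' Variance-tuned bandwidth for the rbf2 kernel
#'
#' The bandwidth is the total variation of the `m` training samples,
#' `sigma^2 = (1/(m-1)^2) * sum_{i,j} ||x_i - x_j||^2`, the double sum running
#' over all ordered pairs including `i = j` (whose terms are zero).
#'
#' @param x Numeric matrix of standardized samples (features x samples) or an
#'   `expression_dataset`.
#' @return Positive scalar `sigma^2`.
#' @export
rbf2_bandwidth <- function(x) {
  mat <- if (inherits(x, "expression_dataset")) x$values else as.matrix(x)
  m <- ncol(mat)
  if (m < 2L) stop("need at least two samples to tune the bandwidth")
  d2 <- pairwise_sq_dists(mat)
  s2 <- 2 * sum(d2[upper.tri(d2)]) / (m - 1L)^2
  if (s2 <= 0) stop("all samples identical: total variation is zero")
  s2
}

pairwise_sq_dists <- function(mat, mat2 = NULL) {
  # columns are samples; returns ncol(mat2) x ncol(mat) when mat2 given
  if (is.null(mat2)) {
    g <- crossprod(mat)
    d <- diag(g)
    d2 <- outer(d, d, "+") - 2 * g
  } else {
    g <- crossprod(mat2, mat)
    d1 <- colSums(mat2^2)
    d2v <- colSums(mat^2)
    d2 <- outer(d1, d2v, "+") - 2 * g
  }
  d2[d2 < 0] <- 0
  d2
}

#' Build a Gram matrix (or rectangular cross-kernel block)
#'
#' Evaluates the kernel on all pairs of sample columns. When a single sample
#' set is given the result is square and its structure (identity-like,
#' constant, or normal) is classified with [classify_gram()]; the structure is
#' the fingerprint used by the bias rules.
#'
#' @param spec A [kernel_spec()]. An `rbf2` spec with unset bandwidth gets its
#'   bandwidth from `x` via [rbf2_bandwidth()].
#' @param x Standardized samples, features x samples (matrix or
#'   `expression_dataset`).
#' @param x2 Optional second sample set; if given, the result is the
#'   rectangular block `K[i, j] = k(x2_i, x_j)` with rows indexed by `x2`
#'   columns, and no structure classification is performed.
#' @param eps_id,eps_flat Structure-classification thresholds, see
#'   [classify_gram()].
#' @return A `gram_matrix` object (square case) or a plain numeric matrix
#'   (cross-kernel case).
#' @export
gram_matrix <- function(spec, x, x2 = NULL, eps_id = 1e-8, eps_flat = 1e-8) {
  stopifnot(inherits(spec, "kernel_spec"))
  mat <- if (inherits(x, "expression_dataset")) x$values else as.matrix(x)
  if (spec$family == "rbf2" && is.na(spec$bandwidth_sq)) {
    spec$bandwidth_sq <- rbf2_bandwidth(mat)
  }
  cross <- !is.null(x2)
  mat2 <- if (cross) {
    m2 <- if (inherits(x2, "expression_dataset")) x2$values else as.matrix(x2)
    if (nrow(m2) != nrow(mat)) stop("feature dimension mismatch between sample sets")
    m2
  } else NULL
  K <- switch(spec$family,
    linear = if (cross) crossprod(mat2, mat) else crossprod(mat),
    quad = (1 + (if (cross) crossprod(mat2, mat) else crossprod(mat)))^2,
    mlp = tanh((if (cross) crossprod(mat2, mat) else crossprod(mat)) - 1),
    rbf = ,
    rbf2 = exp(-pairwise_sq_dists(mat, mat2) / (2 * spec$bandwidth_sq))
  )
  if (cross) return(unname(K))
  K <- unname((K + t(K)) / 2)  # enforce exact symmetry against float noise
  structure(
    list(values = K, spec = spec,
         structure = classify_gram(K, eps_id = eps_id, eps_flat = eps_flat),
         max_offdiag = max_offdiag(K), min_entry = min(K)),
    class = "gram_matrix"
  )
}

max_offdiag <- function(K) {
  if (nrow(K) < 2L) return(0)
  max(abs(K[upper.tri(K)]))
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat("<gram_matrix> ", nrow(x$values), "x", ncol(x$values), " ",
      x$spec$family, " kernel, structure: ", x$structure, "\n", sep = "")
  cat("  max |off-diagonal|: ", format(x$max_offdiag, digits = 4),
      ", min entry: ", format(x$min_entry, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Classify the structure of a square kernel matrix
#'
#' `identity_like`: every off-diagonal entry is below `eps_id` in magnitude
#' and the diagonal is within `eps_id` of one -- the overfitting fingerprint
#' produced by amplified pairwise distances under a narrow Gaussian kernel.
#' `flat_like`: the entry range is below `eps_flat` (a constant matrix,
#' covering the all-ones case) -- the underfitting fingerprint. Anything else
#' is `normal`.
#'
#' @param K A `gram_matrix` or square symmetric numeric matrix.
#' @param eps_id,eps_flat Detection thresholds; the defaults (1e-8) sit far
#'   below any meaningful kernel similarity yet well above float noise.
#' @return One of `"identity_like"`, `"flat_like"`, `"normal"`.
#' @export
classify_gram <- function(K, eps_id = 1e-8, eps_flat = 1e-8) {
  if (inherits(K, "gram_matrix")) K <- K$values
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("classify_gram needs a square matrix")
  if (max_offdiag(K) < eps_id && max(abs(diag(K) - 1)) < eps_id) {
    return("identity_like")
  }
  if (max(K) - min(K) < eps_flat) return("flat_like")
  "normal"
}

#' Summarize pairwise squared sample distances
#'
#' Five-number summary (minimum, quartiles, maximum) of `||x_i - x_j||^2`
#' over all unordered sample pairs. On amplified omics-like data the minimum
#' exceeds 100, which drives the Gaussian Gram matrix to identity.
#'
#' @param x Samples, features x samples (matrix or `expression_dataset`).
#' @return A list with `min_sq`, `quartiles_sq` (25/50/75%), `max_sq`, and
#'   the full vector `d_sq` of pairwise squared distances
#'   (class `distance_summary`).
#' @export
distance_summary <- function(x) {
  mat <- if (inherits(x, "expression_dataset")) x$values else as.matrix(x)
  if (ncol(mat) < 2L) stop("need at least two samples")
  d2 <- pairwise_sq_dists(mat)
  v <- d2[upper.tri(d2)]
  structure(
    list(min_sq = min(v),
         quartiles_sq = unname(stats::quantile(v, c(0.25, 0.5, 0.75))),
         max_sq = max(v), d_sq = v),
    class = "distance_summary"
  )
}

#' @export
print.distance_summary <- function(x, ...) {
  cat("<distance_summary> min ", format(x$min_sq, digits = 5),
      " | quartiles ", paste(format(x$quartiles_sq, digits = 5), collapse = " / "),
      " | max ", format(x$max_sq, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Heatmap of a Gram matrix
#'
#' @param object A `gram_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gram_matrix
#' @export
autoplot.gram_matrix <- function(object, ...) {
  K <- object$values
  df <- tidyr::expand_grid(row = seq_len(nrow(K)), col = seq_len(ncol(K)))
  df$value <- K[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0(object$spec$family, " kernel matrix (",
                                 object$structure, ")"),
                  x = NULL, y = NULL, fill = "k(x_i, x_j)") +
    ggplot2::theme_minimal()
}

#' Export a Gram matrix as delimited text
#'
#' @param K A `gram_matrix`.
#' @param path Output path (tab-delimited, no header).
#' @return `K`, invisibly.
#' @export
write_gram <- function(K, path) {
  stopifnot(inherits(K, "gram_matrix"))
  utils::write.table(K$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(K)
}
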