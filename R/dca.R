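#' Derivative component analysis parameters
#'
#' Controls for the DCA "true signal" extractor: a `level_J`-level per-sample
#' discrete wavelet transform, per-level low-rank reconstruction of the
#' coefficient matrices, and the inverse transform. Detail levels
#' `j <= cutoff_tau` (the finest, noise-dominated scales) are reconstructed
#' from a fixed number of principal components (`detail_components_m`, first
#' PC by default); coarser detail levels and the approximation keep the
#' smallest number of components whose cumulative variance fraction reaches
#' `tail_variability_rho`.
#'
#' @param wavelet Orthogonal Daubechies filter name; `"db8"` default.
#' @param level_J Transform depth (default 7); requires `p >= 2^level_J`.
#' @param cutoff_tau Last detail level treated as fine scale (default 2).
#' @param detail_components_m Components kept at fine detail levels
#'   (default 1).
#' @param tail_variability_rho Cumulative variance fraction kept at coarse
#'   levels and the approximation (default 0.95).
#' @param center_axis PCA centering axis for coefficient matrices:
#'   `"column"` (per sample, default) or `"row"`.
#' @return An object of class `dca_params`.
#' @export
dca_params <- function(wavelet = "db8", level_J = 7L, cutoff_tau = 2L,
                       detail_components_m = 1L, tail_variability_rho = 0.95,
                       center_axis = c("column", "row")) {
  center_axis <- match.arg(center_axis)
  level_J <- as.integer(level_J)
  cutoff_tau <- as.integer(cutoff_tau)
  detail_components_m <- as.integer(detail_components_m)
  if (cutoff_tau < 1L || cutoff_tau > level_J) {
    stop("cutoff_tau must lie in [1, level_J]")
  }
  if (tail_variability_rho <= 0 || tail_variability_rho > 1) {
    stop("tail_variability_rho must lie in (0, 1]")
  }
  if (detail_components_m < 1L) stop("detail_components_m must be >= 1")
  structure(
    list(wavelet = wavelet, level_J = level_J, cutoff_tau = cutoff_tau,
         detail_components_m = detail_components_m,
         tail_variability_rho = tail_variability_rho,
         center_axis = center_axis),
    class = "dca_params"
  )
}

#' @export
print.dca_params <- function(x, ...) {
  cat("<dca_params> ", x$wavelet, ", J = ", x$level_J, ", tau = ",
      x$cutoff_tau, ", m = ", x$detail_components_m, ", rho = ",
      x$tail_variability_rho, "\n", sep = "")
  invisible(x)
}

#' Low-rank reconstruction of a coefficient matrix
#'
#' Column-centers the matrix (per-sample means), keeps the leading principal
#' components of the centered matrix, and restores the means: the
#' reconstruction is `mean term + rank-r SVD approximation`. The rank is
#' either fixed (`m`) or the smallest rank whose cumulative variance fraction
#' reaches `rho`. Component signs are fixed so that the largest-magnitude
#' sample loading of each component is positive, making the output
#' deterministic across LAPACK implementations.
#'
#' @param M Numeric matrix (coefficients x samples), `n >= 2` columns.
#' @param m Fixed number of components (ignored when `rho` is given).
#' @param rho Cumulative variance-explanation threshold in (0, 1].
#' @param center_axis `"column"` (default) or `"row"` mean restoration.
#' @return The reconstructed matrix with attribute `"rank"` = components kept.
#' @export
pca_reconstruct <- function(M, m = NULL, rho = NULL,
                            center_axis = c("column", "row")) {
  center_axis <- match.arg(center_axis)
  M <- as.matrix(M)
  if (ncol(M) < 2L) stop("PCA reconstruction needs at least 2 samples")
  if (is.null(m) && is.null(rho)) stop("give either m or rho")
  if (center_axis == "row") {
    rec <- pca_reconstruct(t(M), m = m, rho = rho, center_axis = "column")
    return(structure(t(rec), rank = attr(rec, "rank")))
  }
  mu <- colMeans(M)
  Cm <- sweep(M, 2L, mu, "-")
  sv <- svd(Cm)
  d2 <- sv$d^2
  total <- sum(d2)
  if (total <= .Machine$double.eps * nrow(M) * ncol(M)) {
    # centered matrix is (numerically) zero: only the mean term survives
    out <- sweep(matrix(0, nrow(M), ncol(M)), 2L, mu, "+")
    return(structure(out, rank = 0L))
  }
  r <- if (!is.null(rho)) {
    if (rho >= 1) sum(d2 > total * .Machine$double.eps)
    else which(cumsum(d2) / total >= rho)[1L]
  } else {
    min(m, length(sv$d))
  }
  r <- max(1L, min(r, length(sv$d)))
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  D <- sv$d[seq_len(r)]
  # deterministic sign: largest-|.| sample loading of each component positive
  for (i in seq_len(r)) {
    peak <- which.max(abs(V[, i]))
    if (V[peak, i] < 0) {
      V[, i] <- -V[, i]
      U[, i] <- -U[, i]
    }
  }
  approx <- U %*% (D * t(V))
  structure(sweep(approx, 2L, mu, "+"), rank = r)
}

#' Extract DCA true signals
#'
#' The full derivative-component-analysis pipeline: per-sample `J`-level DWT,
#' per-level low-rank reconstruction of every detail matrix and the
#' approximation, inverse DWT. The output "true signals" have the same shape
#' as the input and retain the global and subtle structure shared across
#' samples while shedding per-sample system noise.
#'
#' @param X Numeric matrix (p x n) or `expression_dataset`; at least two
#'   samples.
#' @param params A [dca_params()].
#' @param keep_bases Also store the per-level principal-component bases and
#'   column means (needed for inductive projection of unseen samples).
#' @return A `dca_result`: list with `true_signals` (p x n), `params`,
#'   `per_level_rank` (components kept at each detail level and, last, the
#'   approximation), and optionally `bases`.
#' @export
dca_transform <- function(X, params = dca_params(), keep_bases = FALSE) {
  stopifnot(inherits(params, "dca_params"))
  mat <- if (inherits(X, "expression_dataset")) X$values else as.matrix(X)
  if (ncol(mat) < 2L) stop("DCA needs at least two samples")
  ws <- dwt_decompose(mat, level_J = params$level_J, wavelet = params$wavelet)
  J <- params$level_J
  ranks <- integer(J + 1L)
  bases <- if (keep_bases) vector("list", J + 1L) else NULL
  for (j in seq_len(J)) {
    rec <- if (j <= params$cutoff_tau) {
      pca_reconstruct(ws$details[[j]], m = params$detail_components_m,
                      center_axis = params$center_axis)
    } else {
      pca_reconstruct(ws$details[[j]], rho = params$tail_variability_rho,
                      center_axis = params$center_axis)
    }
    ranks[j] <- attr(rec, "rank")
    if (keep_bases) bases[[j]] <- basis_of(ws$details[[j]], ranks[j])
    ws$details[[j]] <- rec
  }
  recA <- pca_reconstruct(ws$approximation, rho = params$tail_variability_rho,
                          center_axis = params$center_axis)
  ranks[J + 1L] <- attr(recA, "rank")
  if (keep_bases) bases[[J + 1L]] <- basis_of(ws$approximation, ranks[J + 1L])
  ws$approximation <- recA
  structure(
    list(true_signals = dwt_reconstruct(ws), params = params,
         per_level_rank = ranks, bases = bases),
    class = "dca_result"
  )
}

# Left singular basis (coefficient-space) of the column-centered matrix,
# used to project unseen sample columns inductively.
basis_of <- function(M, r) {
  if (r == 0L) return(matrix(0, nrow(M), 0L))
  mu <- colMeans(M)
  sv <- svd(sweep(M, 2L, mu, "-"), nu = r, nv = 0)
  sv$u[, seq_len(r), drop = FALSE]
}

#' @export
print.dca_result <- function(x, ...) {
  cat("<dca_result> true signals ", nrow(x$true_signals), " x ",
      ncol(x$true_signals), "\n", sep = "")
  cat("  components kept per level (details 1..J, approximation): ",
      paste(x$per_level_rank, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Inductive transform of new sample columns using stored bases: each level's
# coefficients are centered by the column's own mean, projected onto the
# stored coefficient-space basis, and the mean is restored.
dca_project <- function(mat_new, params, bases) {
  ws <- dwt_decompose(mat_new, level_J = params$level_J,
                      wavelet = params$wavelet)
  J <- params$level_J
  proj <- function(M, U) {
    mu <- colMeans(M)
    Cm <- sweep(M, 2L, mu, "-")
    out <- if (ncol(U) == 0L) matrix(0, nrow(M), ncol(M)) else U %*% crossprod(U, Cm)
    sweep(out, 2L, mu, "+")
  }
  for (j in seq_len(J)) ws$details[[j]] <- proj(ws$details[[j]], bases[[j]])
  ws$approximation <- proj(ws$approximation, bases[[J + 1L]])
  dwt_reconstruct(ws)
}
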