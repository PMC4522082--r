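# Periodized orthogonal discrete wavelet transform.
#
# Daubechies low-pass decomposition filters (standard published constants).
# The high-pass filter is the quadrature mirror hi[k] = (-1)^(k+1) lo[L-1-k]
# (0-based), and synthesis is the transpose of the orthogonal analysis
# operator. Periodization uses circular indexing, so the level-j coefficient
# length is exactly ceil(p / 2^j); odd lengths are first extended by
# duplicating the last entry, which keeps the round trip exact after
# trimming.

DAUBECHIES_LO <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282,
          -0.044088253930794755, -0.017369301001807547,
          0.12874742662047847, 0.0004724845739132828,
          -0.2840155429615469, -0.015829105256349306,
          0.5853546836542067, 0.6756307362972898,
          0.31287159091429995, 0.05441584224310401)
)

wavelet_filters <- function(wavelet) {
  lo <- DAUBECHIES_LO[[wavelet]]
  if (is.null(lo)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(DAUBECHIES_LO), collapse = ", "))
  }
  L <- length(lo)
  hi <- rev(lo) * (-1)^seq_len(L)
  list(lo = lo, hi = hi, length = L)
}

# One level of column-wise periodized DWT. X: N x n. Returns approximation
# and detail matrices, each ceil(N/2) x n.
dwt_step <- function(X, f) {
  N <- nrow(X)
  if (N %% 2L == 1L) {
    X <- rbind(X, X[N, , drop = FALSE])
    N <- N + 1L
  }
  half <- N %/% 2L
  off <- f$length %/% 2L
  a <- matrix(0, half, ncol(X))
  d <- a
  ks <- 2L * (seq_len(half) - 1L) + off
  for (l in seq_len(f$length) - 1L) {
    rows <- X[((ks - l) %% N) + 1L, , drop = FALSE]
    a <- a + f$lo[l + 1L] * rows
    d <- d + f$hi[l + 1L] * rows
  }
  list(a = a, d = d)
}

# Inverse of dwt_step: transpose of the orthogonal analysis operator,
# trimmed to the original (possibly odd) length.
idwt_step <- function(a, d, f, orig_len) {
  half <- nrow(a)
  N <- 2L * half
  off <- f$length %/% 2L
  X <- matrix(0, N, ncol(a))
  ks <- 2L * (seq_len(half) - 1L) + off
  for (l in seq_len(f$length) - 1L) {
    idx <- ((ks - l) %% N) + 1L
    X[idx, ] <- X[idx, ] + f$lo[l + 1L] * a + f$hi[l + 1L] * d
  }
  X[seq_len(orig_len), , drop = FALSE]
}

#' Multi-level column-wise discrete wavelet transform
#'
#' Decomposes each sample column of a features-x-samples matrix into `J`
#' detail coefficient matrices and one approximation matrix, using a
#' periodized orthogonal Daubechies filter bank. The level-`j` coefficient
#' length is exactly `ceiling(p / 2^j)`.
#'
#' @param X Numeric matrix (p x n) or `expression_dataset`.
#' @param level_J Number of decomposition levels; requires `p >= 2^level_J`.
#' @param wavelet Filter name: `"db1"`, `"db2"`, `"db4"`, or `"db8"`.
#' @return A `wavelet_stack`: list with `details` (list of `cD_j`, j = 1..J),
#'   `approximation` (`cA_J`), `original_length`, `level_lengths`, `wavelet`.
#' @export
dwt_decompose <- function(X, level_J = 7L, wavelet = "db8") {
  mat <- if (inherits(X, "expression_dataset")) X$values else as.matrix(X)
  p <- nrow(mat)
  level_J <- as.integer(level_J)
  if (level_J < 1L) stop("level_J must be >= 1")
  if (p < 2^level_J) {
    stop("feature count p = ", p, " is too short for ", level_J,
         " levels (need p >= ", 2^level_J, ")")
  }
  f <- wavelet_filters(wavelet)
  details <- vector("list", level_J)
  cur <- mat
  for (j in seq_len(level_J)) {
    s <- dwt_step(cur, f)
    details[[j]] <- s$d
    cur <- s$a
  }
  structure(
    list(details = details, approximation = cur, original_length = p,
         level_lengths = vapply(details, nrow, integer(1)),
         wavelet = wavelet),
    class = "wavelet_stack"
  )
}

#' Invert a wavelet stack
#'
#' @param ws A `wavelet_stack` from [dwt_decompose()] (its coefficient
#'   matrices may have been modified, e.g. denoised).
#' @return The reconstructed p x n matrix.
#' @export
dwt_reconstruct <- function(ws) {
  stopifnot(inherits(ws, "wavelet_stack"))
  f <- wavelet_filters(ws$wavelet)
  cur <- ws$approximation
  J <- length(ws$details)
  for (j in rev(seq_len(J))) {
    orig <- if (j == 1L) ws$original_length else nrow(ws$details[[j - 1L]])
    cur <- idwt_step(cur, ws$details[[j]], f, orig)
  }
  cur
}

#' @export
print.wavelet_stack <- function(x, ...) {
  cat("<wavelet_stack> ", x$wavelet, ", ", length(x$details),
      " levels, original length ", x$original_length, "\n", sep = "")
  cat("  detail lengths: ", paste(x$level_lengths, collapse = ", "),
      "; approximation: ", nrow(x$approximation), "\n", sep = "")
  invisible(x)
}
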