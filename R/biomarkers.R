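#' Gaussianizing transform for count data
#'
#' Converts non-normally-distributed (count) data to approximately normal
#' values: `L = log(X + 1)` element-wise, each sample column of `L` is
#' centered by its own mean, and the centered column is divided by the
#' column's variance. Datasets already tagged `"normal"` pass through
#' unchanged. (Dividing by the variance rather than the standard deviation
#' follows the procedure's literal definition; a conventional z-score variant
#' is available via `scale = "sd"`.)
#'
#' @param x An `expression_dataset` (non-negative values) or numeric matrix.
#' @param scale `"variance"` (default, literal definition) or `"sd"`
#'   (z-score variant).
#' @return The transformed object; for an `expression_dataset` the
#'   distribution tag becomes `"normal"`.
#' @export
gaussianize <- function(x, scale = c("variance", "sd")) {
  scale <- match.arg(scale)
  if (inherits(x, "expression_dataset")) {
    if (x$distribution_tag == "normal") return(x)
    # an unknown-tagged dataset with negative entries cannot be counts:
    # treat it as already (approximately) normal
    if (x$distribution_tag == "unknown" && any(x$values < 0)) return(x)
  }
  mat <- if (inherits(x, "expression_dataset")) x$values else as.matrix(x)
  if (any(mat < 0)) stop("gaussianize needs non-negative values")
  L <- log(mat + 1)
  mu <- colMeans(L)
  centered <- sweep(L, 2L, mu, "-")
  v <- colSums(centered^2) / (nrow(L) - 1L)
  if (any(v <= 0)) {
    stop("zero-variance column(s) after log transform: ",
         paste(colnames(mat)[v <= 0] %||% which(v <= 0), collapse = ", "))
  }
  denom <- if (scale == "variance") v else sqrt(v)
  out <- sweep(centered, 2L, denom, "/")
  if (inherits(x, "expression_dataset")) {
    x$values <- out
    x$distribution_tag <- "normal"
    x
  } else {
    out
  }
}

#' Rank candidate biomarkers from DCA true signals
#'
#' The phenotype-separation procedure: gaussianize non-normal data, extract
#' DCA true signals, and run a per-feature two-sample t-test (pooled-variance
#' Student test by default; "classic" two-sample test) between the two
#' phenotype groups of the true signals. Features are ranked by ascending
#' p-value. Because DCA denoises aggressively, many p-values are tiny; no
#' multiple-testing correction enters the ranking, but a Benjamini-Hochberg
#' column is attached for information.
#'
#' @param x An `expression_dataset` with both classes present, each with at
#'   least two samples.
#' @param params [dca_params()] for the true-signal extraction.
#' @param var_equal Pooled-variance (TRUE, default) or Welch (FALSE) test.
#' @return A `biomarker_ranking`: `ranking` tibble (`feature_id`,
#'   `t_statistic`, `p_value`, `p_adjusted`, sorted by ascending p-value;
#'   features with zero pooled variance get `p = 1`), plus the true-signal
#'   matrix and labels for coordinate export.
#' @export
rank_biomarkers <- function(x, params = dca_params(), var_equal = TRUE) {
  stopifnot(inherits(x, "expression_dataset"))
  y <- x$labels
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (min(table(y)) < 2L) stop("each class needs at least two samples")
  xg <- gaussianize(x)
  dres <- dca_transform(xg$values, params)
  ts <- dres$true_signals
  g1 <- ts[, y == 1L, drop = FALSE]
  g2 <- ts[, y == -1L, drop = FALSE]
  n1 <- ncol(g1)
  n2 <- ncol(g2)
  m1 <- rowMeans(g1)
  m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(se))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- ifelse(se > 0, (m1 - m2) / se, 0)
  pval <- ifelse(se > 0, 2 * stats::pt(-abs(tstat), df), 1)
  ord <- order(pval, -abs(tstat))
  ranking <- tibble::tibble(
    feature_id = x$feature_ids[ord],
    t_statistic = tstat[ord],
    p_value = pval[ord],
    p_adjusted = stats::p.adjust(pval, method = "BH")[ord]
  )
  structure(
    list(ranking = ranking, true_signals = ts, labels = y,
         sample_ids = x$sample_ids, feature_ids = x$feature_ids,
         params = params),
    class = "biomarker_ranking"
  )
}

#' @export
print.biomarker_ranking <- function(x, ...) {
  cat("<biomarker_ranking> ", nrow(x$ranking), " features ranked\n", sep = "")
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Export top-k biomarker coordinates
#'
#' True-signal values of the top-`k` ranked features for every sample,
#' suitable for external scatter rendering of the phenotype separation
#' (`k = 3` for a 3-D plot).
#'
#' @param ranking A [rank_biomarkers()] result.
#' @param k Number of biomarkers to export (default 3).
#' @return A tibble with one row per sample: `sample_id`, `label`, and one
#'   column per exported biomarker. `k = 0` gives a table with no biomarker
#'   columns.
#' @export
export_top_k <- function(ranking, k = 3L) {
  stopifnot(inherits(ranking, "biomarker_ranking"))
  k <- as.integer(k)
  if (k > nrow(ranking$ranking)) stop("k exceeds the number of ranked features")
  out <- tibble::tibble(sample_id = ranking$sample_ids,
                        label = ranking$labels)
  top <- ranking$ranking$feature_id[seq_len(k)]
  for (fid in top) {
    out[[fid]] <- ranking$true_signals[match(fid, ranking$feature_ids), ]
  }
  out
}

#' Scatter plot of the top two biomarkers
#'
#' @param object A `biomarker_ranking`.
#' @param ... Unused.
#' @return A ggplot object of the top two true-signal coordinates colored by
#'   phenotype.
#' @method autoplot biomarker_ranking
#' @export
autoplot.biomarker_ranking <- function(object, ...) {
  coords <- export_top_k(object, k = 2L)
  ids <- names(coords)[-(1:2)]
  ggplot2::ggplot(coords, ggplot2::aes(x = .data[[ids[1]]],
                                       y = .data[[ids[2]]],
                                       colour = factor(.data$label))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "phenotype",
                  title = "Phenotype separation on top biomarkers") +
    ggplot2::theme_minimal()
}
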