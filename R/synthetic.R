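#' Specification for a synthetic expression dataset
#'
#' The generators emulate the statistical structure that drives each
#' diagnostic-bias mechanism rather than any particular biology: a shared
#' per-feature baseline whose spread mimics the exponential signal
#' amplification of high-throughput profiling (it makes standardized samples
#' strongly correlated and pairwise distances large), i.i.d. per-sample
#' noise, a planted mean shift on a subset of informative features, and a
#' configurable label skew with the majority class labeled `+1`.
#'
#' @param distribution `"normal"` (array-like intensities) or
#'   `"negative_binomial"` (sequencing-like counts with variance
#'   `mu + mu^2/dispersion`).
#' @param n_majority,n_minority Class sizes; majority is labeled `+1`.
#' @param p Feature count (default 2048, a power of two compatible with a
#'   7-level wavelet transform; configurable up to array scale).
#' @param n_informative Number of features carrying the class signal.
#' @param effect_size Class mean shift: in noise-sd units for normal data,
#'   in log2-fold units for counts.
#' @param signal_block_len Informative features are laid out in contiguous
#'   blocks of this length with the shift direction alternating per block
#'   (default 32), emulating co-regulated feature modules: the class signal
#'   is structured across the feature index, as the true-signal model
#'   assumes, rather than flipping sign feature by feature.
#' @param nb_dispersion Negative-binomial size parameter (default 10).
#' @param nb_mean Median baseline count (default 100).
#' @param amplification Spread of the per-feature baseline (sd of baseline
#'   means for normal data; sd of log2 baseline means for counts). Default 4.
#'   Zero removes the shared baseline entirely.
#' @param noise_sd Per-sample noise standard deviation (normal data).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(distribution = c("normal", "negative_binomial"),
                           n_majority = 40L, n_minority = 10L, p = 2048L,
                           n_informative = 50L, effect_size = 1,
                           signal_block_len = 32L,
                           nb_dispersion = 10, nb_mean = 100,
                           amplification = 4, noise_sd = 1, seed = 1L) {
  distribution <- match.arg(distribution)
  n_majority <- as.integer(n_majority)
  n_minority <- as.integer(n_minority)
  p <- as.integer(p)
  n_informative <- as.integer(n_informative)
  if (n_majority < 1L || n_minority < 1L) stop("class sizes must be >= 1")
  if (n_informative < 0L || n_informative > p) {
    stop("n_informative must lie in [0, p]")
  }
  if (amplification < 0) stop("amplification must be non-negative")
  structure(
    list(distribution = distribution, n_majority = n_majority,
         n_minority = n_minority, p = p, n_informative = n_informative,
         effect_size = effect_size,
         signal_block_len = as.integer(signal_block_len),
         nb_dispersion = nb_dispersion,
         nb_mean = nb_mean, amplification = amplification,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$distribution, ", ", x$n_majority, " (+1) vs ",
      x$n_minority, " (-1) samples, p = ", x$p, ", ", x$n_informative,
      " informative at effect ", x$effect_size, " (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic expression dataset
#'
#' Majority-class samples are labeled `+1`. Informative features shift the
#' positive class by `effect_size` (sign alternating across features, so the
#' signal is not a pure global offset). Identical spec (including seed)
#' yields an identical dataset.
#'
#' @param spec A [synthetic_spec()].
#' @return An [expression_dataset()] with the spec attached as attribute
#'   `"spec"`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_majority + spec$n_minority
  labels <- c(rep(1L, spec$n_majority), rep(-1L, spec$n_minority))
  info <- seq_len(spec$n_informative)
  blk <- spec$signal_block_len %||% 32L
  signs <- (-1)^((info - 1L) %/% blk)
  out <- with_seed(spec$seed, {
    if (spec$distribution == "normal") {
      baseline <- stats::rnorm(spec$p, 0, spec$amplification)
      vals <- baseline +
        matrix(stats::rnorm(spec$p * n, 0, spec$noise_sd), spec$p, n)
      if (spec$n_informative > 0L) {
        shift <- signs * spec$effect_size * spec$noise_sd
        vals[info, labels == 1L] <- vals[info, labels == 1L, drop = FALSE] + shift
      }
      vals
    } else {
      log2mu <- stats::rnorm(spec$p, log2(spec$nb_mean), spec$amplification)
      mu <- matrix(2^log2mu, spec$p, n)
      if (spec$n_informative > 0L) {
        lfc <- signs * spec$effect_size
        mu[info, labels == 1L] <- mu[info, labels == 1L, drop = FALSE] * 2^lfc
      }
      matrix(stats::rnbinom(spec$p * n, mu = mu, size = spec$nb_dispersion),
             spec$p, n)
    }
  })
  ds <- expression_dataset(
    out, labels,
    feature_ids = sprintf("f%05d", seq_len(spec$p)),
    sample_ids = sprintf("s%04d", seq_len(n)),
    distribution_tag = if (spec$distribution == "normal") "normal"
                       else "negative_binomial")
  attr(ds, "spec") <- spec
  ds
}

#' Ensure a minimum pairwise distance after standardization
#'
#' Verifies that the minimum pairwise squared distance between per-sample
#' standardized samples reaches `target_min_sq` — the amplified-profiling
#' property that collapses a narrow Gaussian Gram matrix to identity. Since
#' squared distance between standardized samples grows linearly with the
#' feature count, the target is reached by doubling `p` (regenerating from
#' the attached spec) until the verified minimum passes.
#'
#' @param x A generated [expression_dataset()] (must carry its
#'   `synthetic_spec` attribute for regeneration).
#' @param target_min_sq Required minimum pairwise squared distance
#'   (typically 100). Zero or negative returns `x` unchanged.
#' @param max_p Feature-count ceiling for the doubling loop (default 2^15).
#' @return The verified dataset, with attribute `"min_sq"` holding the
#'   achieved minimum.
#' @export
amplify_to_min_distance <- function(x, target_min_sq = 100, max_p = 2^15) {
  stopifnot(inherits(x, "expression_dataset"))
  if (ncol(x$values) < 2L) stop("need at least two samples")
  if (target_min_sq <= 0) return(x)
  repeat {
    ds <- distance_summary(standardize_samples(x$values))
    if (ds$min_sq >= target_min_sq) {
      attr(x, "min_sq") <- ds$min_sq
      return(x)
    }
    if (ds$min_sq == 0) {
      stop("identical samples present: the distance target is unreachable")
    }
    spec <- attr(x, "spec")
    if (is.null(spec) || 2L * spec$p > max_p) {
      stop("cannot reach minimum squared distance ", target_min_sq,
           if (is.null(spec)) " (no generator spec attached)"
           else paste0(" within max_p = ", max_p))
    }
    spec$p <- 2L * spec$p
    x <- generate_dataset(spec)
  }
}

#' Preset generator specs mirroring the benchmark label distributions
#'
#' Five presets reproduce the class counts and distribution families of the
#' benchmark datasets analyzed for diagnostic bias: a gene-array cohort with
#' 13 vs 34 samples, a protein-array cohort with 78 vs 72, an RNA-Seq cohort
#' with 68 vs 475, and two sequencing cohorts with 18 vs 516 and 18 vs 512.
#' Feature counts are scaled down to powers of two (2048; 1024 for the
#' miRNA-like preset) from the original 1k-24k features.
#'
#' A sixth preset, `"skew_1to4"`, is the label-skewness study fixture: a
#' 12-vs-48 normal dataset whose block-structured class signal
#' (200 informative features at effect 0.6) is weak enough that a plain
#' linear LS-SVM collapses onto the majority class, yet is fully recovered
#' from DCA true signals.
#'
#' @param name One of `"breastibc_like"`, `"hcc_like"`, `"kidney_like"`,
#'   `"lgg_rnaseq_like"`, `"lgg_mirnaseq_like"`, `"skew_1to4"`.
#' @param seed Seed stored in the spec.
#' @param ... Overrides passed to [synthetic_spec()] fields.
#' @return A [synthetic_spec()].
#' @export
preset_spec <- function(name = c("breastibc_like", "hcc_like", "kidney_like",
                                 "lgg_rnaseq_like", "lgg_mirnaseq_like",
                                 "skew_1to4"),
                        seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    breastibc_like = list(distribution = "normal", n_majority = 34L,
                          n_minority = 13L),
    hcc_like = list(distribution = "normal", n_majority = 78L,
                    n_minority = 72L),
    kidney_like = list(distribution = "negative_binomial", n_majority = 475L,
                       n_minority = 68L),
    lgg_rnaseq_like = list(distribution = "negative_binomial",
                           n_majority = 516L, n_minority = 18L),
    lgg_mirnaseq_like = list(distribution = "negative_binomial",
                             n_majority = 512L, n_minority = 18L,
                             p = 1024L),
    skew_1to4 = list(distribution = "normal", n_majority = 48L,
                     n_minority = 12L, n_informative = 200L,
                     effect_size = 0.6))
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(synthetic_spec, args)
}
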