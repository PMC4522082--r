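---
title: "Diagnostic biases in kernel-based omics classification and the DCA-SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic biases in kernel-based omics classification and the DCA-SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcasvm)
```

## Scope and model

`dcasvm` diagnoses and repairs three failure modes of kernel classifiers on
high-dimensional omics data, where the number of features `p` (thousands of
genes, probes, m/z ratios or transcripts) dwarfs the number of samples `m`.
The classifier throughout is a least-squares SVM: the soft-margin SVM with
its inequality constraints replaced by equalities, so that training reduces
to one `(m+1) × (m+1)` linear system

$$\begin{pmatrix} 0 & \mathbf{1}^\top \\ \mathbf{1} & K + I/C \end{pmatrix}
\begin{pmatrix} b \\ \alpha \end{pmatrix} =
\begin{pmatrix} 0 \\ y \end{pmatrix},$$

with `K` the kernel matrix of the standardized training samples, ridge
`mu = 1/C` on its diagonal, and the first row enforcing `sum(alpha) = 0`.
The decision rule is `sign(sum_i alpha_i k(x_i, x') + b)`, with an exact
zero mapped to `+1` (the deterministic tie rule; the majority class is
mapped to `+1` throughout). The solution is dense — unlike the C-SVM there
is no sparsity, so "support vectors" in reports mean all samples with
`|alpha_i| > 1e-12`.

Two conventions deserve a note. First, the penalty is `C = 1` everywhere,
deliberately generic: re-scaling `C` per dataset would make the multiplier
magnitudes incomparable between balanced and skewed cohorts, and the
multipliers are themselves diagnostic evidence here. No grid search is
performed. Second, every sample column is standardized to mean 0, variance
1 (denominator `p - 1`) before any kernel evaluation. This per-sample
scaling is fit-free — a test sample is scaled by its own mean and variance
— so there is no train/test leakage in the scaling step, and the same
dataset can be split arbitrarily without re-fitting a scaler. A per-feature
axis switch exists in `standardize_samples()` but per-sample scaling is the
default, because the distance analysis below concerns distances between
standardized *samples*.

## Kernels and their degenerate structures

Five kernel families are implemented (`kernel_spec()`): linear `x·x'`,
Gaussian `rbf` `exp(-||x-x'||^2 / 2σ²)` with `σ² = 1`, `rbf2` with the
bandwidth tuned to the total variation of the training samples
`σ² = (m-1)^{-2} Σ_{i,j} ||x_i - x_j||²` (ordered pairs, the `i = j` zero
terms included — `rbf2_bandwidth()` documents the convention), quadratic
`(1 + x·x')²`, and `mlp` `tanh(x·x' - 1)`. The `mlp` kernel is not positive
semidefinite; it is included *because* it breaks, and the solver falls back
to a pseudoinverse solution with a warning if its system is singular. No
PSD repair is attempted.

`classify_gram()` fingerprints a kernel matrix as

- `identity_like` — every off-diagonal below `eps_id` and diagonal within
  `eps_id` of 1;
- `flat_like` — entry range below `eps_flat` (constant matrix, covering
  the all-ones case);
- `normal` — anything else.

Both thresholds default to `1e-8`: far below any kernel similarity that
could influence a decision value, far above double-precision noise. They
are configurable, but the phenomena they detect are not marginal — on
amplified data the rbf off-diagonals are below `1e-20`, and the saturated
mlp matrix is constant to the last bit.

## Why the biases arise

**Overfitting.** High-throughput profiling amplifies expression levels
exponentially, so even after per-sample standardization the squared
distance between any two samples exceeds 100 (the squared distance between
standardized samples is `2(p-1)(1 - r)` for sample correlation `r`, and
`p` is in the thousands). Under `rbf` with `σ² = 1` every cross-sample
kernel value is at most `exp(-50) ≈ 2·10⁻²²`: `K` is the identity. The
dual system then gives `b = mean(y)` exactly and every far-away test
sample a decision value of `b`, i.e. the majority vote. Accuracy collapses
to the majority-count ratio while sensitivity is 1 and specificity 0 — the
closed form is exercised directly in the test suite.

**Label skewness.** With a `normal` Gram and skewed labels, more
support-vector weight carries the majority sign and the intercept is
positive; weak minority structure is swamped and specificity collapses
even though accuracy looks fine. The explicit form has accuracy at the
majority-count floor; the implicit form sits above it.

**Underfitting.** Omics samples share a strong per-feature baseline, so
standardized samples are highly correlated and their inner products are
large: `tanh(x·x' - 1)` saturates at 1 for every pair including the
diagonal. A constant kernel matrix carries no information; per-fold
predictions are a constant sign and accuracy hovers near chance. (Note a
subtlety visible in cross-validation: with a constant predictor, a fold's
training majority is anticorrelated with its test composition, so fold-mean
accuracy sits slightly *below* 0.5 — around 0.42-0.45 on balanced data —
rather than exactly at it.)

## The bias rules and their calibration

`classify_bias()` applies a rule cascade over the aggregated metrics,
the label counts, and the Gram structure:

1. identity-like Gram, specificity ≤ `delta_spec` (0.05), accuracy within
   `delta_acc` of the majority ratio → **overfitting**;
2. flat Gram, accuracy ≤ 0.5 + `delta_rand` (0.1) → **underfitting**;
3. normal Gram, sensitivity-specificity gap ≥ `delta_gap` (0.30), and
   accuracy - ratio ≤ `delta_acc` → **explicit label skew**;
4. normal Gram, the same gap, accuracy - ratio > `delta_acc` →
   **implicit label skew**;
5. otherwise **none**.

The explicit/implicit boundary is one-sided by design. The published
benchmark rows that motivate the taxonomy have explicit-skew accuracy gaps
ranging from -0.029 to +0.023 (explicit skew can sit well *below* the
floor: a weak classifier that mostly parrots the majority) while the
implicit-skew row sits at +0.0275; `delta_acc = 0.025` is the separating
value, and a symmetric window cannot separate them at all. These defaults
are calibration choices of this package, exposed in `bias_thresholds()`
and recorded in each report.

The diagnostic index `beta = -log2(a) - log2((s+p)/2)` condenses a run
into one number: 0 for a perfect diagnosis, about 1 when the
sensitivity/specificity pair averages one half (accuracy carried entirely
by the majority class), about 2 for near-random diagnosis, `+Inf` when
`s + p = 0`. It is reported to 4 decimals.

### NaN is a value

When a biased classifier predicts every sample positive, `TN = FN = 0` and
the negative predictive ratio is `0/0`. The package propagates this as
`NaN` through per-fold metrics and through aggregation (a single NaN fold
makes the aggregated NPR NaN), because a NaN NPR *is* the fingerprint of
the all-majority failure and averaging it away would hide exactly what the
report exists to show.

## Derivative component analysis

`dca_transform()` extracts "true signals" `X*` of the same shape as the
input:

1. **Decompose.** Each sample column undergoes a `J`-level discrete
   wavelet transform (default `db8`, `J = 7`). The transform is
   periodized, implemented with circular indexing, so the level-`j`
   coefficient length is exactly `ceiling(p / 2^j)`; odd lengths are
   extended by duplicating the last entry, which keeps the round trip
   exact. The filter bank is the standard Daubechies family (`db1`-`db8`
   taps embedded as constants); synthesis is the transpose of the
   orthogonal analysis operator, so reconstruction with untouched
   coefficients reproduces the input to `1e-8` at any length.
2. **Reconstruct per level.** Each detail matrix `cD_j` (`p_j × n`) and
   the approximation `cA_J` are replaced by a low-rank reconstruction:
   per-sample (column) means are removed, the centered matrix is
   approximated by its leading singular components, and the means are
   restored. Fine detail levels `j ≤ τ` (default `τ = 2`) keep a fixed
   number of components (default 1, the first principal component);
   coarser levels and the approximation keep the smallest rank reaching a
   cumulative variance fraction `ρ = 0.95`. Component signs are fixed so
   the largest-magnitude sample loading is positive, making the output
   deterministic across LAPACK builds. Centering per column (per sample)
   rather than per row is a deliberate reading of an ambiguous convention;
   a `center_axis` switch exposes the alternative.
3. **Invert.** The inverse transform of the reconstructed stack, trimmed
   to the original length, is `X*`.

The rationale: per-sample noise is isotropic at every scale and is
discarded by the low-rank step, while structure shared across samples —
the strong per-feature baseline and any class signal that is *structured
across the feature index* — survives. A signal that flips sign from one
feature to the next lives entirely at the finest scale and is destroyed by
first-PC reconstruction; a signal organized in blocks or smooth profiles
lives at coarse scales and is retained. That asymmetry is not a flaw; it
is the model of what a "true signal" is.

## DCA-SVM

`dca_svm()` standardizes, extracts true signals, and trains a
linear-kernel LS-SVM on them (`C = 1`). For prediction the unseen samples
must themselves be transformed; the reference procedure is silent on how,
so both defensible readings are implemented:

- `transform_mode = "joint"` (default): the stored training matrix and the
  new samples are transformed together and the new columns extracted. This
  is transductive — the per-level bases see unlabeled test structure — and
  reports flag the mode; labels are never involved.
- `transform_mode = "inductive"`: the per-level principal-component bases
  are frozen at fit time and test coefficients are projected onto them
  (each test column centered by its own mean, projected, mean restored).

Both modes recover held-out labels on the skewed fixture; the joint mode
is the default because it matches how a per-fold pipeline naturally runs.

## Evaluation schemes and experiments

`eval_scheme()` provides k-fold CV, leave-one-out, and Monte-Carlo
independent splits (`fixed_half`: exactly `ceiling(n/2)` training samples
per repetition, default 500 repetitions; `bernoulli_half`: a fair coin per
sample, repetitions with an empty side redrawn). All randomness flows from
the scheme seed; equal seeds give byte-identical reports. K-fold is a
plain random partition by default; a stratified option exists for small
skewed fixtures where an unstratified fold could lose the minority class
entirely (making specificity NaN) or leave a single-class training fold
(an error by design, with the fold index in the message). Per-fold metrics
are averaged (mean ± sd), not pooled, matching the "± std" reporting
format.

`run_experiment()` binds everything: split, standardize, fit, predict,
score, aggregate, attach the full-data Gram structure and per-fold signed
multiplier reports, classify the bias. By default evaluation remaps the
positive class to the majority-count type, the convention under which the
biased patterns read sensitivity 1 / specificity 0.

## The synthetic generators

No real cohorts ship with the package; `synthetic_spec()` +
`generate_dataset()` emulate the statistical properties the diagnostics
respond to, not any particular biology:

- **Shared per-feature baseline** (`amplification`, default sd 4 for
  normal data, sd of log2 means for counts): emulates exponential signal
  amplification. It makes standardized samples correlate around 0.94,
  which simultaneously (a) keeps pairwise squared distances
  `2(p-1)(1-r)` above 100 at `p = 2048`, collapsing the rbf Gram to
  identity, and (b) saturates the mlp Gram flat.
- **Class signal in contiguous blocks** (`n_informative` features at
  `effect_size`, laid out in blocks of `signal_block_len = 32` with
  alternating block sign): co-regulated-module structure, placed at
  wavelet scales the DCA reconstruction retains.
- **Distributions**: Gaussian intensities, or negative-binomial counts
  with variance `mu + mu²/dispersion` (dispersion 10, median baseline 100)
  and log2-fold class effects.
- **Label skew**: majority class labeled `+1`; presets mirror the
  benchmark label distributions (13 vs 34 gene-array-like, 78 vs 72
  protein-array-like, 68 vs 475 and 18 vs 516/512 sequencing-like).
  Feature counts are scaled to `p = 2048` (1024 for the miRNA-like
  preset): a power of two compatible with `J = 7`, small enough for fast
  tests, and large enough for every distance/saturation mechanism; `p` is
  configurable up to array scale.

`amplify_to_min_distance()` verifies the distance property after
standardization and doubles `p` (regenerating from the attached spec)
until the target is met, erroring on duplicated samples for which no
dimension suffices.

The `skew_1to4` preset is the label-skewness study fixture: 12 vs 48
samples, 200 informative features at effect 0.6. At these settings the
class signal is far below the per-sample noise floor in the raw data — a
plain linear LS-SVM predicts nearly everything positive (specificity
0-0.2 across seeds) — while DCA removes enough noise that the same LS-SVM
on true signals recovers both classes (sensitivity and specificity ≥ 0.93
across seeds). These values were fixed once, from the mechanism, when the
fixture was designed.

What the generators do *not* emulate: realistic gene-gene correlation
beyond the shared baseline, batch effects, platform-specific noise, or
library-size variation. Passing tests on these fixtures demonstrates the
*mechanisms* — they are necessary, not sufficient, evidence about any real
cohort.

## Biomarker ranking

`rank_biomarkers()` implements the phenotype-separation procedure:
non-normal (count) data pass through the gaussianizing transform
`Y = E(log(X+1)) / var(log(X+1))` — each sample column of `log1p(X)`
centered by its own mean and divided by its own *variance* (the literal
definition; a conventional sd-scaled variant sits behind
`scale = "sd"`) — then DCA true signals, then a per-feature pooled-variance
two-sample t-test ("classic" Student test; Welch behind `var_equal =
FALSE`), ranked by ascending p-value. Because DCA denoises aggressively,
p-values are tiny en masse; the ranking uses raw p-values and a
Benjamini-Hochberg column is attached for information only. Features with
zero pooled variance get `p = 1`. `export_top_k()` emits the top-`k`
true-signal coordinates per sample for external scatter rendering
(`k = 3` for the customary 3-D view), and `autoplot()` draws the top two.

## Numerical choices, in one place

- LS-SVM system solved densely by LU (`solve`); singular or non-finite
  systems fall back to a Moore-Penrose least-squares solution with a
  warning.
- `sign(0) → +1` everywhere a decision value is thresholded.
- Label-count ties resolve the majority label to `+1`.
- Gram symmetry is enforced as `(K + Kᵀ)/2` against float asymmetry.
- Structure thresholds `eps_id = eps_flat = 1e-8`; bias-rule thresholds
  `delta_spec = 0.05`, `delta_acc = 0.025`, `delta_rand = 0.1`,
  `delta_gap = 0.30`.
- PCA rank at `ρ = 1` keeps all numerically nonzero singular values; a
  numerically zero centered matrix keeps rank 0 (mean term only).
- Quartiles use the default empirical quantile definition (type 7).

## Limitations

- Binary phenotypes only; no multi-class extension.
- The mlp kernel's indefiniteness is reported, not repaired.
- The joint transform mode shares unlabeled test structure with training;
  use the inductive mode when that is unacceptable.
- Bias-rule thresholds are calibrated to published benchmark patterns and
  to the package's fixtures; cohorts with very mild skew or very small
  `m` may need adjusted thresholds.
- Test problem sizes (`p = 2048`, cohorts of 47-150 samples) are
  deliberately modest; all code paths accept array-scale inputs.
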