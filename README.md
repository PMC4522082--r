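# dcasvm

Diagnostic-bias detection and derivative component analysis for
kernel-based omics classification.

## The problem

Classifiers trained on high-throughput omics profiles (gene arrays, protein
arrays, RNA-Seq/miRNA-Seq) routinely report accuracies that look clinical
while silently ignoring one phenotype. With `m` standardized samples
`x_i ∈ ℝ^p` (p ≫ m) and labels `y_i ∈ {−1,+1}`, a kernel classifier can be
*biased* in three distinct ways, each with a Gram-matrix fingerprint:

- **Overfitting bias.** Profiling platforms amplify molecular signals
  exponentially, so pairwise squared distances `‖x_i − x_j‖²` exceed 100
  even after per-sample standardization. Under a Gaussian kernel
  `k(x, x′) = exp(−‖x − x′‖²/2σ²)` with `σ² = 1`, every off-diagonal kernel
  value is below `exp(−50) ≈ 10⁻²²`: the kernel matrix is the identity, the
  decision function collapses to the intercept, and every test sample is
  called the majority class. Accuracy equals the majority-count ratio —
  pure illusion.
- **Label-skewness bias.** Skewed label counts (e.g. 68 vs 475) tilt both
  the support-vector weights and the intercept `b` toward the majority
  class. The *explicit* form shows accuracy at the majority-count floor
  with wildly imbalanced sensitivity/specificity; the *implicit* form shows
  healthy-looking accuracy above the floor but the same imbalance.
- **Underfitting bias.** A saturating kernel such as
  `mlp: tanh(x·x′ − 1)` on strongly correlated samples produces a constant
  (all-ones) kernel matrix with no discriminating power: accuracy near
  chance.

This package implements the full diagnostic framework around a
least-squares SVM, plus the feature extractor that conquers the skew bias:
**derivative component analysis (DCA)** — a J-level discrete wavelet
transform of each sample, per-level low-rank PCA reconstruction of the
coefficient matrices (first principal component at the finest `τ` levels,
95 % cumulative variance elsewhere), and the inverse transform. The
denoised "true signals" feed a linear-kernel LS-SVM (**DCA-SVM**).

## The model

The LS-SVM dual is one linear system. With kernel matrix `K`, penalty
`C = 1` (ridge `μ = 1/C` on the diagonal):

```
[ 0   1ᵀ      ] [ b ]   [ 0 ]
[ 1   K + I/C ] [ α ] = [ y ],     f(x′) = sign( Σᵢ αᵢ k(xᵢ, x′) + b )
```

The constraint row enforces `Σ αᵢ = 0`. Reported as evidence: the signed
multipliers (`|αᵢ|` carrying the class sign of sample `i`), the sign of
`b`, the Gram structure (`identity_like` / `flat_like` / `normal`), and the
diagnostic index

```
β = −log₂(accuracy) − log₂((sensitivity + specificity)/2)
```

(0 = perfect; ≈1 = accuracy carried by the majority class; ≈2 = random).

## Worked example

A 12-vs-48 synthetic cohort (2048 features, weak block-structured class
signal) under 5-fold cross-validation:

```r
library(dcasvm)
ds <- generate_dataset(preset_spec("skew_1to4", seed = 1))
sch <- eval_scheme("kfold", k = 5, seed = 101)
run_experiment(ds, "linear", sch, stratify = TRUE)
#> <bias_experiment> linear under <eval_scheme> 5-fold CV (seed 101)
#>   accuracy     80.16 ± 03.02
#>   sensitivity  100.00 ± 00.00
#>   specificity  00.00 ± 00.00
#>   npr          NaN ± NaN
#>   ppr          80.16 ± 03.02
#> <bias_report> explicit_label_skew
#>   gram: normal | majority ratio: 0.8000 | acc gap: +0.0016 | sens-spec gap: 1.0000
#>   alpha signs: 38 positive / 9 negative; b sign +
#>   diagnostic index beta: 1.3190
```

The plain linear LS-SVM's 80 % accuracy is exactly the majority-count
ratio: it never recognises a single minority sample (specificity 0, NPR
NaN because nothing is ever predicted negative), and the positively-signed
support-vector weights and positive intercept show why. The same data
through DCA-SVM:

```r
run_experiment(ds, "dca_svm", sch, stratify = TRUE)
#> <bias_experiment> dca_svm under <eval_scheme> 5-fold CV (seed 101)
#>   accuracy     100.00 ± 00.00
#>   sensitivity  100.00 ± 00.00
#>   specificity  100.00 ± 00.00
#>   npr          100.00 ± 00.00
#>   ppr          100.00 ± 00.00
#> <bias_report> none
#>   diagnostic index beta: 0.0000
```

Every result object is tidyverse-friendly: `tidy()` gives per-fold metrics
or per-sample multipliers, `glance()` a one-row summary, `autoplot()` a
ggplot of the Gram matrix, fold metrics, or biomarker separation.

A thin command-line wrapper is included (`inst/cli/diagbias.R`) with
subcommands `simulate`, `diagnose`, `dca-transform`, `biomarkers`,
`bias-report`.

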