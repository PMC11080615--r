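# perseclock

Chronological-age prediction from DNA methylation with a channel-attention
perceptron.

## The problem

Epigenetic clocks predict a person's age from the methylation fractions
(beta values, in [0, 1]) measured at CpG loci by Illumina arrays. Most
published clocks are sparse linear models over a few hundred loci selected
for one platform; restricting to the 24,516 CpG loci shared by the 27K,
450K and 850K platforms makes a single model applicable to samples from any
of them, but leaves the model to decide which of those loci matter.
`perseclock` implements a clock that learns that weighting itself: a
multilayer perceptron regressor preceded by a squeeze-and-excitation (SE)
channel-attention block that up-weights age-informative loci and
down-weights noise loci before the regression.

## The model

A sample's beta vector `x` of length `L = r * c * K` (full panel:
`24,516 = 3 * 6 * 1,362`) is reshaped so that consecutive loci fall into
consecutive channels; channel `k` holds the `r * c = 18` loci with index
`≡ k (mod K)`. The attention block computes

- **squeeze** — per-channel means `s_k = mean(x in channel k)` (global
  average pooling, 1,362 values on the full panel);
- **excitation** — `g = sigmoid(W2 · relu(W1 · s + b1) + b2)` with a
  bottleneck of width `K / 16`, giving one gate `g_k ∈ (0, 1)` per channel;
- **scale** — every value in channel `k` is multiplied by `g_k`.

The rescaled vector feeds a 4-hidden-layer MLP (32 units each; linear →
LeakyReLU → BatchNorm1d(32) → Dropout(0.1)) ending in one linear output:
the predicted age in years. Training minimises MSE with Adam
(lr 0.05, batch 512, ≤ 150 epochs), early-stopping at the lowest validation
loss with checkpoint restore; the canonical shuffle-split of 10,589 samples
at fractions 0.81/0.09/0.10 gives 8,577/953/1,059
train/validation/test samples. Accuracy is reported as R², MAE, MSE and the
median absolute error (Med), plus per-tissue mean signed error. A
`plain_mlp` variant — the identical head without the attention block — is
the built-in ablation baseline.

The network, including backpropagation through the SE block and batch
normalization, is implemented in base R matrix algebra inside the package
and verified against numerical differentiation in the test suite.

## Worked example

Everything runs on synthetic cohorts with known age-informative loci, so no
array downloads are needed:

```r
library(perseclock)

cohort <- generate_cohort(synthetic_spec(n_samples = 600, n_loci = 108,
                                         n_informative = 12, seed = 42))
cohort$beta
#> <beta_matrix: 600 samples x 108 loci, 0.0% missing>

fit <- fit_clock(cohort$beta, cohort$meta, clock_config(channels = 6),
                 train_config(batch_size = 128, seed = 42))
glance(fit)
#> # A tibble: 1 × 8
#>   epochs_run best_epoch best_val_loss test_n test_r_squared test_mae test_mse
#>        <int>      <int>         <dbl>  <int>          <dbl>    <dbl>    <dbl>
#> 1         72         52          4.50     60          0.995     1.66     4.44
```

Training stopped after 72 epochs and restored epoch 52, whose validation
MSE (4.50 yr²) was lowest; on the 60 held-out samples the clock reaches
R² = 0.995 and MAE = 1.66 years (test Med, the robust headline metric, is
in `fit$test_metrics$med`). Per-tissue bias, the usual clock diagnostic:

```r
per_group_error_summary(fit$test_predictions, cohort$meta, "tissue")
#> # A tibble: 4 × 5   (first rows)
#>   group      n mean_error   med   mae
#> 1 blood      6     -0.160 1.76   1.76
#> 2 brain      7     -1.37  0.991  1.54
#> 3 breast     7     -0.374 0.825  1.17
```

And the learned attention, inspected on held-out samples — channels
containing age-informative loci receive systematically higher gates:

```r
channel_gate_profile(fit$model, unclass(cohort$beta)[fit$split$test, ])
#> # A tibble: 6 × 2      (channels 1-4 and 6 contain informative loci)
#>   channel  gate
#> 1       1 0.319
#> 2       2 0.661
#> 3       3 0.639
#> 4       4 0.696
#> 5       5 0.203   <- pure-noise channel
#> 6       6 0.713
```

`autoplot(fit)`, `plot_predictions()`, `plot_gate_profile()` and
`plot_group_errors()` give the corresponding figures. Real array data
enters through `read_beta_matrix()` (GEO-series-matrix-style TSV/CSV),
`filter_samples_by_missingness()` (drops samples with more than 50%
missing), `intersect_loci()` (aligns to a shared locus panel) and
`impute_missing()` (regression-based imputation). A command-line pipeline
(`simulate`, `preprocess`, `train`, `predict`, `evaluate`,
`compare-baseline`) lives in `inst/scripts/perseclock.R`.

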