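---
title: "Methods: a channel-attention perceptron clock for DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a channel-attention perceptron clock for DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Model

`perseclock` predicts chronological age (years) from a vector of
methylation beta values over a fixed, ordered panel of CpG loci. The input
is used raw: beta values already live in [0, 1] and carry biological
meaning at that scale, so no standardization is applied anywhere in the
pipeline.

The network is a perceptron regressor with a squeeze-and-excitation (SE)
channel-attention front end. The length-`L` input is viewed as a
`block_rows x block_cols x channels` tensor with `L = r * c * K`; element
`i` goes to channel `((i - 1) mod K) + 1`, so *consecutive loci occupy
consecutive channels* and each channel collects `r * c` loci spread evenly
across the panel. On the full cross-platform panel this is
`24,516 = 3 * 6 * 1,362`, i.e. 1,362 channels of 18 loci. Within-channel
placement is row-major, but both pooling and channel scaling are invariant
to it (a property the tests check), so only the locus-to-channel map is
load-bearing.

Attention proceeds squeeze → excitation → scale:

* squeeze: `s_k` = mean of the `r * c` values in channel `k`;
* excitation: `g = sigmoid(W2 relu(W1 s + b1) + b2)` with bottleneck width
  `max(1, K %/% se_reduction)`;
* scale: every value in channel `k` is multiplied by the gate
  `g_k ∈ (0, 1)`.

The rescaled, flattened vector feeds the regression head:
`hidden_depth` hidden layers of `hidden_width` units, each
linear → LeakyReLU → batch normalization → dropout, then a single linear
output unit. The `plain_mlp` variant applies the identical head directly to
the input with no attention parameters at all; it exists solely as the
ablation baseline for what the gates contribute.

### Assumptions

* Age information is distributed over many loci, each individually weak and
  monotone-ish in age; a dense nonlinear model over the shared panel can
  pool them without per-platform feature selection.
* Channels are an arbitrary partition of the panel, not a biological unit;
  attention works because a gate that amplifies a channel amplifies the
  informative loci inside it relative to channels holding none.
* Input matrices are fully imputed before training or prediction; the model
  refuses `NA`s rather than guessing.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `block_rows`, `block_cols`, `channels` | 3, 6, 1362 | – | full-panel geometry; `r * c * K` must equal the panel length |
| `se_reduction` | 16 (capped at `channels`) | – | SENet's published bottleneck convention; capped so small test geometries keep a valid (width ≥ 1) bottleneck |
| `hidden_width`, `hidden_depth` | 32, 4 | units, layers | reference head geometry |
| `dropout_rate` | 0.1 | prob. | reference regularization |
| `leaky_slope` | 0.01 | – | framework-conventional LeakyReLU slope |
| `learning_rate` | 0.05 | – | reference Adam step size |
| `batch_size` | 512 | samples | reference; last partial batch kept, size-1 batches skipped (batch statistics need n ≥ 2) |
| `max_epochs` | 150 | epochs | reference budget |
| `patience` | 20 | epochs | operationalizes "stop at the lowest validation loss" without manual curve watching |
| `split_fractions` | 0.81/0.09/0.10 | – | under floor–floor–remainder these reproduce the canonical 8,577/953/1,059 partition of 10,589 samples |

Where the architecture's source description is silent — the excitation
bottleneck width, its inner ReLU and sigmoid output, the LeakyReLU slope,
Adam's `beta1/beta2/eps` — we adopt the corresponding framework and SENet
conventions and expose them as configuration where a user could reasonably
disagree (`se_reduction`, `leaky_slope`). The hidden-layer ordering
(activation before batch normalization, dropout last) follows the order the
components are conventionally listed in for this architecture.

## Numerical choices

* **Initialization**: every linear layer draws weights and biases from
  `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`, reproducibly from the model seed.
* **Batch normalization**: eps `1e-5`; training normalizes with biased
  batch variance and tracks running statistics with momentum 0.1 (unbiased
  variance in the running estimate); evaluation always uses running
  statistics, so prediction is deterministic, batch-size invariant and
  works on single samples.
* **Early stopping**: after each epoch the validation MSE is computed in
  evaluation mode; the full parameter state (running statistics included)
  of the best epoch is snapshotted and restored at the end, so the returned
  model reproduces `best_val_loss` to machine precision.
* **Determinism**: one seed controls the split permutation, parameter
  initialization, epoch shuffling and dropout masks. Two runs with the same
  seed and data produce identical histories and parameters (single-threaded
  BLAS; the test suite asserts bitwise-equal histories).
* **Gradients**: backpropagation through the SE block, LeakyReLU, batch
  normalization (batch-statistics path) and dropout is hand-derived and
  checked against central-difference numerical gradients at tolerance
  `1e-4` in the tests.
* **Degenerate inputs**: length mismatches, non-finite values, unimputed
  matrices and panel-order mismatches are hard errors with the offending
  quantity named; a non-finite training loss aborts with the epoch number
  rather than silently diverging.

## Preprocessing

Samples with *strictly more than* `max_missing_fraction` (default 50%)
missing loci are dropped; a sample at exactly the threshold is kept.
`intersect_loci()` reorders a matrix to a user-supplied locus panel —
the panel file is the single source of locus ordering, shared between
training and prediction — inserting fully missing columns for absent loci
and warning when more than 10% of the panel is absent.

`impute_missing()` performs regression-based imputation in the
methyLImp spirit: each locus with missing entries is regressed (ordinary
least squares) on the `max_predictors = 5` loci most `|r|`-correlated with
it over the samples where it is observed, and the missing entries are
predicted and clamped to [0, 1]. Predictor columns that are themselves
incomplete enter with their missing entries provisionally replaced by their
observed mean: when fully observed predictor loci exist this is exactly a
regression on them, and under scattered missingness (where *no* locus may
be complete) it degrades gracefully instead of collapsing to locus means.
Correlation ties are broken by column order, deterministically. Collinear
predictors are handled by the pivoting least-squares fit (redundant
coefficients set to zero). Fallbacks: fewer than two observed samples →
observed mean; a locus observed nowhere → global observed mean, logged.
Observed values are never modified by any preprocessing step, a pipeline
invariant the tests assert.

## The synthetic cohort generator

Real multi-platform methylation compendia cannot ship with a package, so
every end-to-end claim is exercised on synthetic cohorts with known ground
truth. `generate_cohort()` emulates the features the clock actually relies
on:

* beta values bounded in [0, 1];
* a minority of *informative* loci following
  `clamp01(plogis(a_j + b_j z_i) + eps)` with `z_i` the cohort-standardized
  age — a saturating logistic drift that keeps values in range and mimics
  monotone methylation change with age; `|b_j|` is drawn from
  `[effect_scale/2, effect_scale]` with random sign;
* a majority of age-independent loci drawn from a Beta distribution
  (concentration 50) around a per-locus baseline, plus the same Gaussian
  observation noise;
* round-robin tissue (8 labels), platform (27K/450K/850K) and dataset ids,
  so per-group reporting paths run;
* optional uniform missingness with the masked values retained for
  imputation scoring.

Defaults — 2,000 samples, 432 loci (geometry 3 × 6 × 24), 40 informative,
ages uniform on [0, 100] years, `effect_scale = 2`, `noise_sd = 0.03` —
define the standard cohort used by the end-to-end tests and the acceptance
script. Ages are standardized inside the generator so `effect_scale` means
the same thing across age ranges. The age range covers a full human
lifespan as in typical multi-cohort compendia; `effect_scale = 2` gives
informative loci a beta-value dynamic range of roughly 0.4–0.8 across the
cohort, comparable to strong clock CpGs, and `noise_sd = 0.03` is a
realistic array noise level on the beta scale.

What the generator does **not** emulate: platform-specific probe chemistry
and detection noise, batch and cohort effects, cell-composition
heterogeneity, correlated blocks of neighbouring CpGs, and non-monotone age
trajectories. Passing the recovery tests therefore shows the architecture
and optimizer can find distributed monotone signal under noise — not that
the clock attains any particular accuracy on real arrays.

## Problem sizes in the test and acceptance runs

Unit tests use geometries of 2–8 channels (36–144 loci) and cohorts of
40–500 samples; the gradient checks run on a 24-locus model. The end-to-end
recovery, attention-separation and baseline-comparison checks train on the
standard cohort (2,000 × 432, three training seeds, both variants; about
half a minute per full set on one CPU). The metric oracle comparison uses
1,000 random prediction vectors at tolerance `1e-10`; the canonical-split
check uses `n = 10,589` directly.

## Known limitations

* Training cost is R-level matrix algebra: fine for hundreds of loci, but
  the full 24,516-locus panel at batch 512 is substantially slower than a
  GPU framework; the package targets method transparency and desk-scale
  validation, not large-scale refitting.
* The attention gates are per-channel, and channels are index-interleaved
  partitions; gate values identify informative *channels*, not individual
  CpGs.
* Early stopping uses a single validation split; no cross-validation or
  stratified splitting (an unstratified shuffle matches the reference
  protocol; stratification is deliberately not implemented).
* The imputation scheme is a deliberately simple regression imputer with a
  documented contract, not a reimplementation of any published imputation
  package's exact estimates.
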