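# Shared fixtures, all generated in code.

# small geometry: 3 x 6 x 6 = 108 loci, quick to train
small_cfg <- function() clock_config(channels = 6L)

small_cohort <- function(seed = 1, n = 300, n_loci = 108, n_informative = 12,
                         noise_sd = 0.03, ...) {
  generate_cohort(
    synthetic_spec(n_samples = n, n_loci = n_loci,
                   n_informative = n_informative, noise_sd = noise_sd,
                   seed = seed, ...),
    clock_config(channels = n_loci %/% 18L))
}

tiny_beta <- function(n = 4, l = 6, seed = 99) {
  set.seed(seed)
  beta_matrix(matrix(runif(n * l), n, l,
                     dimnames = list(sprintf("S%02d", seq_len(n)),
                                     sprintf("cg%05d", seq_len(l)))))
}

# the standard cohort and trained fits used by the slower end-to-end checks;
# memoised so several test files can share one training run
.fit_cache <- new.env(parent = emptyenv())

standard_cohort <- function() {
  if (is.null(.fit_cache$cohort)) {
    .fit_cache$cohort <- generate_cohort(synthetic_spec())
  }
  .fit_cache$cohort
}

standard_fit <- function(variant, seed) {
  key <- paste(variant, seed, sep = "_")
  if (is.null(.fit_cache[[key]])) {
    cohort <- standard_cohort()
    .fit_cache[[key]] <- fit_clock(cohort$beta, cohort$meta,
                                   clock_config(channels = 24L),
                                   train_config(seed = seed),
                                   variant = variant)
  }
  .fit_cache[[key]]
}
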