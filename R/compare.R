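#' Compare the attention clock with a plain-perceptron baseline
#'
#' Trains the channel-attention clock and a plain MLP with the identical
#' regression head on the same cohort, with the same split, initialization
#' stream and dropout stream for each seed, and reports the held-out test
#' metrics side by side. This is the ablation that isolates what channel
#' attention adds: with several seeds, compare the median `med` (median
#' absolute error) between variants.
#'
#' @param bm A fully imputed [beta_matrix()].
#' @param meta Sample metadata (see [as_sample_meta()]).
#' @param clock_cfg A [clock_config()] matching `ncol(bm)`.
#' @param cfg A [train_config()]; its `seed` is replaced by each element of
#'   `seeds` in turn.
#' @param seeds Integer vector of seeds (default `1:3`).
#' @return Tibble with one row per variant x seed: `variant`, `seed`, and
#'   the test-set `n`, `r_squared`, `mae`, `mse`, `med`.
#' @export
compare_baseline <- function(bm, meta, clock_cfg, cfg = train_config(),
                             seeds = 1:3) {
  purrr::map_dfr(seeds, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- as.integer(s)
    purrr::map_dfr(c("perseclock", "plain_mlp"), function(v) {
      fit <- fit_clock(bm, meta, clock_cfg, cfg_s, variant = v)
      dplyr::bind_cols(tibble::tibble(variant = v, seed = as.integer(s)),
                       fit$test_metrics)
    })
  })
}
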