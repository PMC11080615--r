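#' Specification of a synthetic methylation cohort
#'
#' Describes a simulated cohort in which a minority of CpG loci drift
#' monotonically with age on the logit scale (a saturating trajectory that
#' keeps beta values naturally inside `[0, 1]`) while the remaining loci are
#' age-independent noise. The defaults define the package's standard test
#' cohort: 2,000 samples over 432 loci (geometry `3 x 6 x 24`), 40 of them
#' age-informative, observation noise of 0.03 on the beta scale.
#'
#' @param n_samples Number of samples.
#' @param n_loci Number of CpG loci; must match the paired clock geometry.
#' @param n_informative Number of age-informative loci (`<= n_loci`).
#' @param age_low,age_high Age range in years; ages are drawn uniformly.
#' @param effect_scale Magnitude of the age slope on the logit scale; each
#'   informative locus gets `|slope|` in `[effect_scale/2, effect_scale]`
#'   with random sign, applied to the cohort-standardized age.
#' @param noise_sd Gaussian observation noise on the beta scale, applied to
#'   every locus before clamping to `[0, 1]`.
#' @param missing_fraction Fraction of entries masked as missing
#'   (see [inject_missingness()]).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 2000L, n_loci = 432L,
                           n_informative = 40L, age_low = 0, age_high = 100,
                           effect_scale = 2, noise_sd = 0.03,
                           missing_fraction = 0, seed = 1L) {
  stopifnot(n_samples >= 1, n_loci >= 1,
            n_informative >= 0, n_informative <= n_loci,
            age_low < age_high, age_low >= 0,
            effect_scale > 0, noise_sd >= 0,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(n_samples = as.integer(n_samples),
                 n_loci = as.integer(n_loci),
                 n_informative = as.integer(n_informative),
                 age_low = age_low, age_high = age_high,
                 effect_scale = effect_scale, noise_sd = noise_sd,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

synthetic_tissues <- c("blood", "saliva", "buccal", "brain",
                       "liver", "muscle", "skin", "breast")

#' Generate a synthetic methylation cohort with known age signal
#'
#' Ages are uniform on `[age_low, age_high]` and standardized within the
#' cohort. Informative locus `j` follows
#' `beta_ij = clamp01(plogis(a_j + b_j * z_i) + eps)` with
#' `z_i` the standardized age, `eps ~ N(0, noise_sd)`, intercept
#' `a_j ~ U(-1, 1)` and slope `|b_j| in [effect_scale/2, effect_scale]` with
#' random sign. Non-informative loci are Beta-distributed around a per-locus
#' baseline plus the same noise. Tissue labels rotate through a fixed list
#' of eight tissues, platforms through 27K/450K/850K and dataset ids through
#' five synthetic accessions, so per-group reports are exercised.
#'
#' @param spec A [synthetic_spec()].
#' @param cfg The paired [clock_config()]; `spec$n_loci` must equal
#'   `input_length(cfg)`. Defaults to the `3 x 6` geometry with
#'   `n_loci / 18` channels.
#' @return List with `beta` (a [beta_matrix()]), `meta` (sample-metadata
#'   tibble) and `truth` (list: `informative_locus_ids`, tibble `loci` with
#'   per-locus `intercept`, `slope`, `channel`, and
#'   `informative_channels`).
#' @export
generate_cohort <- function(spec, cfg = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(cfg)) {
    if (spec$n_loci %% 18L != 0L) {
      stop("n_loci must be divisible by 18 for the default 3 x 6 geometry.",
           call. = FALSE)
    }
    cfg <- clock_config(channels = spec$n_loci %/% 18L)
  }
  stopifnot(inherits(cfg, "clock_config"))
  if (input_length(cfg) != spec$n_loci) {
    stop(sprintf("n_loci = %d but the clock geometry implies %d.",
                 spec$n_loci, input_length(cfg)), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_samples
  L <- spec$n_loci
  sample_ids <- sprintf("SYN%05d", seq_len(n))
  locus_ids <- sprintf("cg%08d", seq_len(L))

  age <- stats::runif(n, spec$age_low, spec$age_high)
  z <- (age - mean(age)) / stats::sd(age)

  informative <- sort(sample.int(L, spec$n_informative))
  intercept <- stats::runif(spec$n_informative, -1, 1)
  slope <- sample(c(-1, 1), spec$n_informative, replace = TRUE) *
    stats::runif(spec$n_informative, spec$effect_scale / 2, spec$effect_scale)

  values <- matrix(NA_real_, n, L, dimnames = list(sample_ids, locus_ids))
  base_mu <- stats::runif(L, 0.05, 0.95)
  conc <- 50
  for (j in seq_len(L)) {
    k <- match(j, informative)
    if (!is.na(k)) {
      mu <- stats::plogis(intercept[k] + slope[k] * z)
    } else {
      mu <- stats::rbeta(n, base_mu[j] * conc, (1 - base_mu[j]) * conc)
    }
    eps <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else 0
    values[, j] <- pmin(1, pmax(0, mu + eps))
  }
  bm <- beta_matrix(values)

  meta <- tibble::tibble(
    sample_id = sample_ids,
    age = age,
    tissue = rep_len(synthetic_tissues, n),
    platform = rep_len(c("27K", "450K", "850K"), n),
    dataset_id = rep_len(sprintf("SYNSET%02d", 1:5), n))

  channel <- channel_of(cfg)
  truth <- list(
    informative_locus_ids = locus_ids[informative],
    loci = tibble::tibble(locus_id = locus_ids[informative],
                          intercept = intercept,
                          slope = slope,
                          channel = channel[informative]),
    informative_channels = sort(unique(channel[informative])))

  if (spec$missing_fraction > 0) {
    bm <- inject_missingness(bm, spec$missing_fraction, seed = spec$seed)
  }
  list(beta = bm, meta = meta, truth = truth)
}

#' Mask a fixed fraction of beta-matrix entries
#'
#' Masks exactly `round(fraction * n_entries)` entries chosen uniformly at
#' random. The masked values are kept in the `masked_truth` attribute so
#' imputation accuracy can be scored against them.
#'
#' @param bm A [beta_matrix()].
#' @param fraction Fraction of entries to mask, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [beta_matrix()] with the chosen entries set to `NA`;
#'   [masked_truth()] retrieves the hidden values.
#' @export
inject_missingness <- function(bm, fraction, seed = 1L) {
  stopifnot(is_beta_matrix(bm), fraction >= 0, fraction < 1)
  if (fraction == 0) return(bm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  m <- unclass(bm)
  n_mask <- round(fraction * length(m))
  idx <- sample.int(length(m), n_mask)
  rc <- arrayInd(idx, dim(m))
  hidden <- tibble::tibble(sample_id = rownames(m)[rc[, 1]],
                           locus_id = colnames(m)[rc[, 2]],
                           value = m[idx])
  m[idx] <- NA_real_
  out <- structure(m, class = c("beta_matrix", "matrix"))
  attr(out, "masked_truth") <- hidden
  out
}

#' @rdname inject_missingness
#' @export
masked_truth <- function(bm) attr(bm, "masked_truth")

#' Score imputation accuracy against hidden masked values
#'
#' @param imputed A [beta_matrix()] after [impute_missing()].
#' @param hidden The `masked_truth` tibble from [inject_missingness()].
#' @return Root-mean-square error between imputed and true values over the
#'   masked entries.
#' @export
imputation_rmse <- function(imputed, hidden) {
  stopifnot(is_beta_matrix(imputed), is.data.frame(hidden))
  got <- unclass(imputed)[cbind(match(hidden$sample_id, rownames(imputed)),
                                match(hidden$locus_id, colnames(imputed)))]
  sqrt(mean((got - hidden$value)^2))
}
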