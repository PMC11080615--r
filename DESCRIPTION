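Package: perseclock
Title: Channel-Attention Perceptron Clocks for DNA Methylation Age
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts chronological age from DNA-methylation beta values at
    CpG loci shared across Illumina 27K/450K/850K arrays using a perceptron
    regressor augmented with squeeze-and-excitation channel attention, so
    that age-informative loci are up-weighted and noise loci down-weighted
    before the regression head. Provides beta-matrix input/output with
    missing-value handling, sample filtering, locus-panel intersection and
    regression-based imputation; deterministic training with Adam, early
    stopping at the lowest validation loss and checkpoint restore; the
    standard evaluation metrics (R-squared, MAE, MSE and median absolute
    error) with per-tissue signed-error summaries; a plain-perceptron
    baseline for ablation; and a synthetic-cohort generator with known
    age-informative loci for end-to-end testing without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
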