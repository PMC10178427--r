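Package: ramandelay
Title: Detecting Pre-Analytical Storage Delay in Serum Raman Spectra with 1D Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting the pre-analytical
    storage delay (measurement day 0-7) of blood serum samples from their 1D
    Raman spectra. Provides a synthetic serum-spectrum generator with a
    patient-dependent fluorescence background and a storage-dependent aging
    signal, fluorescence baseline correction at two strengths (rolling-minimum
    and asymmetric least squares), day-group dataset construction with class
    balancing, a 1D convolutional neural network classifier trained with AdamW
    and cross-entropy, Monte-Carlo cross-validation with max-test-accuracy
    model selection, per-class accuracy and chance-level summaries, and
    spectral clustering for cohort-restricted training.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
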