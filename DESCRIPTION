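Package: eegstate
Title: Riemannian Tangent-Space Pipeline for EEG Mental-State Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting attention-related mental
    states (normal, channelized attention, diverted attention,
    startle/surprise) from multichannel EEG. Provides a seeded synthetic EEG
    generator with known class covariance structure and artifact ground
    truth, FIR band-pass filtering and fixed-length epoching, peak-to-peak
    amplitude gating, cross-validated per-channel rejection thresholds with
    channel interpolation, ICA-based blink removal using a frontal surrogate
    channel, Riemannian geometry on symmetric positive-definite covariance
    matrices (affine-invariant distance, Frechet mean, exponential and
    logarithmic maps, tangent-space vectorization), xDawn-augmented
    covariance features with Fisher geodesic discriminant filtering and
    PCA/ANOVA selection, stratified cross-validated ensemble classification
    with soft voting, and band-power spectral summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
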