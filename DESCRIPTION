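Package: flywake
Title: Feature-Based Discrimination of Wakefulness and Anesthesia in Fly LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for discriminating wakefulness from anesthesia or sleep in
    multi-channel Drosophila local field potential (LFP) recordings using
    univariate time-series features. Provides a synthetic multi-fly, multi-dataset
    LFP epoch generator with condition-dependent autocorrelation timescale and
    variance, bipolar re-referencing and line-noise preprocessing, a registry of
    named time-series features (autocorrelation, stationarity, distribution,
    spectral, entropy, extrema and nonlinear families), per-feature nearest-median
    classification with leave-one-fly-out cross-validation, cross-dataset
    evaluation with batch normalization, permutation nulls with per-channel FDR
    correction, a within-fly effect-direction consistency statistic, and
    correlation-distance clustering of discriminative features.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
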