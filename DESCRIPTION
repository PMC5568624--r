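Package: sleeprank
Title: Feature Ranking and Rank Aggregation for Sleep-Stage Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative pipeline for filter-based feature ranking in
    automatic sleep-stage classification from polysomnography (PSG). Computes
    a 49-dimensional feature vector per 30-second epoch (time-domain
    statistics, Hjorth parameters, wavelet-packet band energies, spectral and
    amplitude entropies, nonlinear complexity measures and the Itakura
    spectral distance to a wake autoregressive model), ranks features with
    seven filter methods (ReliefF, MRMR-MID/MIQ, Fisher score, chi-square,
    information gain, CMIM), aggregates rankings by Borda count and robust
    rank aggregation, and evaluates selection stability (bootstrap Tanimoto
    index), between-method similarity and classification accuracy (1-NN and
    a small feed-forward network) with Kneedle knee-point selection of the
    optimal feature count. Includes a seeded synthetic PSG cohort generator
    so the whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
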