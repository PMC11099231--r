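Package: driftdecode
Title: Drift-Diffusion Modeling and Single-Trial EEG Decoding of
    Distractor Effects on Categorical Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for studying how task-irrelevant
    distractors modulate categorical decision-making. Couples
    hierarchical Bayesian drift-diffusion modeling of choice and
    reaction-time data (Wiener first-passage-time likelihood, adaptive
    Metropolis-within-Gibbs sampling, DIC model comparison,
    Gelman-Rubin diagnostics) with single-trial sliding-window EEG
    discrimination (leave-one-trial-out logistic decoding, ROC-area Az,
    permutation significance thresholds, forward-model scalp
    topographies), temporal clustering of topographies into components,
    and cluster-based group bootstrap statistics. Includes a synthetic
    generator emulating a three-condition distractor design so every
    stage is testable without the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
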