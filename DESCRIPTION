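Package: chaoscope
Title: Nonlinear Dynamics of Chaotic Time Series and Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified toolkit for quantifying the nonlinear dynamics of
    uniformly sampled time series, aimed at multichannel interictal EEG.
    Implements three estimators of Lyapunov exponents from scalar data
    (the Wolf neighbor-replacement method, the Rosenstein mean
    log-divergence method, and the Sano-Sawada local-Jacobian spectrum
    with Gram-Schmidt reorthonormalization), delay-coordinate embedding
    with data-driven delay (mutual information) and dimension (false
    nearest neighbors), multiscale sample entropy, and normalized
    Lempel-Ziv complexity.  Ships generators for the classical benchmark
    systems (logistic map, Henon map, Rossler flow) and for synthetic
    21-channel EEG with focal sharp-wave transients, a channel-wise
    analysis pipeline with longitudinal trend tracking, and spherical
    spline scalp topography.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
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
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
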