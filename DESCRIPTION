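Package: desync
Title: Inferring Cellular Stochastic Noise from Population-Level Circadian Damping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating cellular stochastic noise from the damping
    rate of population-level circadian bioluminescence recordings. Implements
    Hodrick-Prescott detrending, zero-phase Butterworth smoothing and
    matrix-pencil estimation of damped-sinusoid parameters; wavelet and
    Hilbert-transform analysis of single-cell traces with bootstrap tests of
    group damping differences; a stochastic (tau-leaping/Gillespie) eight-state
    circadian feedback-loop model with system-volume calibration against an
    observed damping rate and parameter-knockdown scans; robust plate
    normalization, moment/correlation/regression summaries and Hotelling T2
    hit-calling for high-throughput screens; and seeded synthetic-data
    generators for single-cell, dose-response and plate-screen experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    Matrix,
    deSolve,
    MASS,
    readr,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
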