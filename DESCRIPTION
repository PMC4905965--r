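Package: usemnet
Title: Unified Structural Equation Modeling of Directed Connectivity in
    Multivariate Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating directed (effective) connectivity among
    regions of interest from multivariate time series with a unified
    structural equation model: a lag-1 multivariate autoregressive SEM in
    which every variable appears twice, as its original series and as a
    one-step-offset copy.  Includes a structural-VAR simulator with
    cohort-wise coefficient schedules, artifact censoring and
    standardization of time-series panels, maximum-likelihood fitting of
    multi-group covariance structures in RAM form, chi-square based fit
    indices (RMSEA with noncentral chi-square confidence bounds, the
    Browne-Cudeck criterion, CFI), modification-index guided
    specification search, and per-cohort trend analysis of path
    coefficients including hypergeometric edge-set overlap tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
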