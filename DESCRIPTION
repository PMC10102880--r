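Package: ppcm
Title: Population Partly Conditional Mean Estimation for Longitudinal Data
    with Dropout, Death and Practice Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian model-based estimation of the population partly
    conditional mean (PPCM), the finite-population mean of a longitudinal
    outcome among units still alive at a given wave, when auxiliary
    covariates are observed for every unit of the target population but the
    outcome only for a non-representative probability sample subject to
    monotone dropout. Working models for the outcome and response process
    are fitted per wave either with Bayesian additive regression trees using
    a sparse Dirichlet splitting prior or with conjugate Bayesian linear and
    probit regressions; population outcome and response histories are then
    imputed by sequential Monte Carlo integration, with triangular-prior
    sensitivity parameters for nonignorable dropout among survivors and for
    practice effects on repeated testing. The package also provides
    design-based and model-assisted comparison estimators (sample mean,
    cell-weighted Horvitz-Thompson, GREG, MRP), a scenario simulator for
    benchmarking the estimators on synthetic finite populations, and
    replicate-level bias, SD, MSE and coverage reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rjags,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
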