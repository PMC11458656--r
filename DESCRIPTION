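Package: mpadose
Title: Population Pharmacokinetics and Dose Optimization of Mycophenolate
    in Pediatric Kidney Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation tools built around a population pharmacokinetic
    model of mycophenolic acid (MPA) in pediatric kidney-transplant
    recipients: a two-compartment disposition model with Erlang-type
    absorption, allometric weight scaling and a serum-albumin covariate on
    clearance.  The package generates virtual pediatric populations,
    simulates steady-state exposure (AUC0-12) under the licensed
    body-surface-area based mycophenolate mofetil (MMF) starting dose and
    under weight-band dosing charts, derives such charts from clearance and
    a target AUC, performs MAP-Bayes estimation of individual parameters
    from sparse sampling for model-informed precision dosing, and provides
    goodness-of-fit and prediction-corrected visual predictive check
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
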