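Package: serinepk
Title: Population Pharmacokinetics of L-Serine with Endogenous Baseline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic modelling and simulation of orally
    administered L-serine (AST-001) superposed on continuous zero-order
    endogenous production. Implements the analytic two-compartment model with
    zero-order absorption and linear elimination, log-normal inter-individual
    variability with a V1-CL covariance block and proportional residual error,
    FOCE-with-interaction estimation with likelihood-ratio testing, bootstrap
    confidence intervals and eta-shrinkage diagnostics, phase-I trial
    simulation, baseline-adjusted non-compartmental exposure metrics, and
    allometry-based pediatric fixed-dose band selection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    tibble
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    dplyr,
    ggplot2
Config/testthat/edition: 3
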