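Package: combopkpd
Title: Two-Compartment PK/PD Simulation and AUC-Effect Scoring for Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates intravenous two-compartment drug disposition with
    fixed-step Euler or fourth-order Runge-Kutta integration, couples tissue
    concentration to percent cell-growth inhibition through four-parameter
    Hill dose-response curves, and scores anticancer-drug plus itraconazole
    combination scenarios by the area under the effect-time curve
    (AUC_effect). Includes closed-form biexponential oracles, multiple-dosing
    extensions (direct integration, superposition, steady-state
    approximation), nonlinear least-squares recovery of pharmacokinetic and
    dose-response parameters, a synthetic-data generator for concentration-
    time profiles and MTT-style dose-response replicates, and bundled
    reference parameter sets for gemcitabine, 5-fluorouracil and
    itraconazole.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
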