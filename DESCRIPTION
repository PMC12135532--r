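Package: fosfopk
Title: Population Pharmacokinetics and Dose Optimization of Intravenous
    Fosfomycin Under Kidney Replacement Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population pharmacokinetic modelling of intravenous fosfomycin in
    critically ill patients with and without kidney replacement therapy (KRT).
    Implements a two-compartment infusion model with parallel body and dialysis
    clearance, covariate relationships for kidney function (eGFR), dialysate
    flow and time-varying peripheral volume, forward simulation under
    continuous and prolonged-intermittent KRT schedules, Monte Carlo
    probability-of-target-attainment (PTA) analysis against AUC/MIC and
    time-above-MIC targets with dose recommendation, Laplace-approximation
    maximum marginal-likelihood estimation with stepwise covariate selection,
    prediction-corrected visual predictive checks, and a synthetic-data
    generator emulating four pooled clinical study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
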