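Package: leukopred
Title: Bayesian State-Space Prediction of Leukocyte Counts During
    6-Mercaptopurine Maintenance Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear Gaussian state-space models for forecasting peripheral
    blood leukocyte counts of paediatric acute lymphoblastic leukaemia patients
    during 6-mercaptopurine maintenance chemotherapy.  Implements a
    two-compartment kinetic-pharmacodynamic model (TCM), its stochastic
    volatility extension that uses C-reactive protein as an infection
    surrogate (TCM-CRP), an eight-compartment ordinary differential equation
    comparator model of 6-mercaptopurine pharmacokinetics and leukopoiesis,
    and a naive mean baseline.  Provides an extended Kalman filter marginal
    likelihood, maximum a posteriori estimation over log parameters with
    Gaussian priors, rolling-origin time-series cross-validation with
    coverage, MAE and RMSE metrics, and a synthetic-patient simulator for
    download-free testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
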