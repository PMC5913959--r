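Package: tigepk
Title: Population Pharmacokinetics of High-Dose Tigecycline in Critically
    Ill Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of plasma tigecycline
    concentrations under a high-dose regimen (200 mg loading dose, 100 mg
    every 12 h as 30-min infusions) in patients with sepsis or septic
    shock.  Implements a closed-form two-compartment disposition model
    with zero-order infusion input, log-normal interindividual and
    interoccasion random effects and a combined additive plus
    proportional residual error model, estimated by a first-order
    conditional (Laplace-at-the-mode) approximation to the marginal
    likelihood.  Provides conditional weighted residuals, shrinkage,
    visual predictive checks, nonparametric bootstrap, empirical-Bayes
    covariate screening, secondary parameter derivations, a synthetic
    study generator emulating the sampling design, and a pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
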