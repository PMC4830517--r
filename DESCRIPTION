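Package: jmclaims
Title: Joint Models of Emergency-Claims Trajectories and Survival in
    Elderly Insureds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint modelling of yearly emergency medical claim counts and
    time to death for insured subjects aged 65 and over.  A linear mixed
    model on log1p-transformed claim counts is linked to a proportional
    hazards model through a recency-weighted cumulative effect of the
    expected claims trajectory, so that recent demand for care weighs more
    heavily on the death hazard than old demand.  The package provides
    maximum-likelihood estimation of the joint model with a cubic B-spline
    log-baseline hazard and pseudo-adaptive Gauss-Hermite quadrature,
    dynamic individualized survival prediction updated as new claims are
    recorded, prediction-error evaluation under absolute loss, and a
    synthetic-cohort generator emulating a large insurance portfolio with
    heavy administrative censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    survival,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
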