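Package: patgp
Title: Stochastic Growth, Progression and Regression Modelling of
    Pilocytic Astrocytoma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a Moran-type tumor growth and progression model of
    pilocytic astrocytoma (PA) with two mutation stages and two tumor
    endpoints (benign PA-I at fixation, aggressive PA-II at the first
    second-hit cell).  Provides the embedded jump chain and a seeded
    trajectory simulator, exact finite-population absorption probabilities
    by first-step analysis, the asymptotic absorption probability
    1/I0(2*sqrt(gamma)) and the closed-form regression function built from
    modified Bessel functions, calibration of the risk coefficient gamma
    from binomial cohort counts, quantitative prediction of post-resection
    regression probability from residual tumor volume, and synthetic-cohort
    generators for end-to-end parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
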