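Package: bstar
Title: Bayesian Structured Additive Regression for Spatial Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian generalized geo-additive mixed models for binary
    household-survey outcomes: parametric fixed effects, second-order
    random-walk (RW2) smooths of continuous covariates, and BYM-style
    structured (intrinsic CAR) plus unstructured zone-level random effects,
    with exact Polya-Gamma augmented Gibbs sampling and DIC model comparison.
    Includes a synthetic household-survey generator mirroring the structure
    of the Ethiopia Socioeconomic Survey (binary food-insecurity outcome,
    zone adjacency graph) for parameter-recovery experiments, and a
    descriptive-statistics stage (contingency tables, prevalences,
    chi-square and summary t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
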