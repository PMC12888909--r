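Package: riskuq
Title: Individual-Level Uncertainty in Multifactorial Breast Cancer Risk
    Prediction with Missing Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the uncertainty in an individual's predicted
    absolute breast-cancer risk that is caused by missing risk-factor
    data.  Missing covariates are drawn by multivariate imputation by
    chained equations (MICE) fitted to a reference cohort, each completed
    profile is pushed through a multiplicative absolute-risk model with
    competing mortality, and the resulting Monte Carlo risk distribution
    yields a point estimate, a 95% uncertainty interval, probabilities of
    falling in each NICE risk category, and the probability of risk-category
    reclassification when groups of risk factors (questionnaire factors,
    mammographic density, genetic factors) are successively measured.
    Includes a Gaussian-copula generator for synthetic reference cohorts
    with the mixed-type covariate structure of breast-cancer risk studies,
    and Gelman-Rubin convergence diagnostics for the imputation chains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
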