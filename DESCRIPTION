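Package: ppimr
Title: Postprandial Inflammation Analysis with Path Models and Mendelian
    Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for meal-induced inflammatory responses in
    metabolic-challenge cohorts. Features postprandial glucose and
    triglyceride curves (incremental areas, rises from fasting, windowed
    peak concentrations), characterizes inflammatory-marker responses
    (responder fractions, percent changes, cross-sectional coefficients of
    variation, variance-heterogeneity and repeated-measures interaction
    tests), ranks predictors of the GlycA response with cross-validated
    random forests and multivariable regression, fits manifest-variable
    path models with maximum-likelihood fit indices (CFI, TLI, RMSEA), and
    provides a from-scratch two-sample Mendelian-randomization toolkit
    (harmonization, IVW, MR-Egger, Cochran's Q, MR-PRESSO, MR-RAPS,
    leave-one-out, instrument strength) plus a network-MR mediation layer.
    Includes seeded generators for synthetic cohorts and GWAS summary
    statistics with planted ground truth so every stage is testable
    without access-controlled study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    car,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
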