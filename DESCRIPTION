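Package: nbcea
Title: Net-Benefit Regression and Cost-Effectiveness Acceptability Curves
    for Household Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cost-effectiveness analysis of two-arm health
    interventions observed through household surveys, built around the
    net-benefit regression framework. Attributes societal-perspective
    per-household costs from out-of-pocket and health-system components,
    computes incremental cost-effectiveness ratios (overall and stratified)
    with cost-effectiveness-plane classification, fits simple, covariate-
    adjusted and interaction net-benefit regressions across a grid of
    willingness-to-pay ceiling ratios, and derives cost-effectiveness
    acceptability curves (CEAC) and CEAC-based confidence intervals for the
    ICER. Includes a calibrated synthetic two-district cohort generator for
    validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
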