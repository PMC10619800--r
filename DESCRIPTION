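Package: censquaids
Title: Censored Quadratic Almost Ideal Demand Systems for Household
    Budget Microdata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation pipeline for censored Quadratic Almost Ideal
    Demand Systems (QUAIDS) from household purchase-diary microdata:
    quality-adjusted unit values with geographic price imputation,
    Tornqvist and Cobb-Douglas price aggregators, the Shonkwiler-Yen
    two-step correction for zero purchases (per-category probit cdf/pdf
    augmentation), the Blundell-Robin residual-inclusion correction for
    total-expenditure endogeneity, joint estimation by iterated feasible
    generalized least squares (nonlinear seemingly unrelated regression)
    with optional adding-up, homogeneity and symmetry restrictions,
    Marshallian price and expenditure elasticities with delta-method
    standard errors, income-quintile subgroup elasticities, first-order
    tax counterfactuals, and a synthetic microdata generator with known
    ground truth for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
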