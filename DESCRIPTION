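Package: adversitree
Title: Weighted Classification Trees for Early-Life Risk Subgroup Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers subgroups of children at elevated risk of adolescent
    suicidal ideation and other adverse outcomes from dichotomized early-life
    risk factors. Grows a survey-weighted binary classification tree under a
    minimum-node-size rule, designates every node high, moderate or low risk
    relative to the cohort base rate, prunes risk-homogeneous subtrees,
    extracts high-risk subgroup profiles as conjunctions of predictor
    conditions, ports them to an external cohort through a closest-proxy
    predictor mapping, and evaluates screening diagnostics (sensitivity,
    specificity, predictive values) against a stepwise logistic-regression
    comparator. A synthetic cohort generator with planted high-risk subgroups
    makes the whole pipeline testable without access to restricted survey
    microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
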