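Package: arhlscreen
Title: Community Screening Toolkit for Age-Related Hearing Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for community screening of age-related hearing loss
    (presbycusis): an 18-indicator cumulative risk-factor score with
    high/low stratification, scoring of the Hearing Handicap Inventory for
    the Elderly screening version (HHIE-s), the two-step two-tone screening
    audiometry decision tree, pure-tone-audiometry reference classification
    (better-ear four-frequency average and grade bands), triage
    recommendations, and screening-test validation statistics (sensitivity,
    specificity, predictive values, Cohen's kappa, ROC/AUC with
    Youden-optimal cutoff, Spearman correlation, and exhaustive
    reconstruction of integer confusion matrices from rounded published
    metrics). Includes a seeded synthetic cohort generator whose
    hearing-loss probability follows a configurable logistic model with a
    calibrated intercept, so the full screening pipeline can be exercised
    and validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caret,
    optparse,
    withr
Config/testthat/edition: 3
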