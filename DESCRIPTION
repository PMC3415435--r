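Package: cypddi
Title: Literature-Rule-Based Prediction and EMR Assessment of CYP-Mediated
    Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for predicting cytochrome P450
    (CYP) mediated drug-drug interactions (DDIs) from rule-based literature
    screening and for assessing their clinical effect on myopathy risk in
    electronic medical record (EMR) data. Provides a sentence-pattern
    scanner and information-extraction rule engine for in vitro
    substrate/inhibitor evidence, enzyme-based DDI pair prediction with
    Ki-binned potency classes, retrospective 30-day exposure-window cohort
    construction from OMOP-like tables, additive and synergistic
    logistic-regression DDI tests with the relative-risk statistic
    RR = Risk12/(Risk1+Risk2), Bonferroni control, CYP enrichment, power
    simulation, and synthetic-data generators with known ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
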