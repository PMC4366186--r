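Package: glycoscreen
Title: Opportunistic Screening for Dysglycemia with FINDRISC and HbA1c
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for evaluating opportunistic screening strategies for
    undiagnosed diabetes and pre-diabetes. Implements the Finnish Diabetes
    Risk Score (FINDRISC) from raw questionnaire and anthropometric data,
    OGTT-based glycemic classification into five mutually exclusive classes,
    diagnostic accuracy metrics (sensitivity, specificity, predictive values,
    screening yield) for single and combined (parallel/serial) index tests,
    empirical ROC curves with trapezoidal and rank-based AUC, DeLong's test
    for correlated AUCs, shortest-distance optimal cutoff selection,
    survey-weighted prevalence estimation, and a seeded generator of
    NHANES-like synthetic cohorts with a five-class glycemic mixture
    structure so the whole pipeline is testable without any data download.
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
    utils,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
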