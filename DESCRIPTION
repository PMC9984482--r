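Package: ppvstroke
Title: Pulse Pressure Variability and Functional Outcome in Acute Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes pulse-pressure variability (PPV) indices (SD, CV,
    successive variation, average real variability, maximum-minimum
    difference, maximal successive change) from serial blood-pressure
    readings over a 72-hour monitoring window, labels stroke functional
    outcome from the modified Rankin Scale (dichotomized and
    severity-adjusted rules), and runs the associated inference battery:
    Spearman rank correlation, Mann-Whitney U tests, multivariable
    logistic regression with odds ratios per 10 mmHg, and ROC analysis
    with DeLong confidence intervals and Youden cut-offs. Includes a
    synthetic cohort generator with a logistic outcome link for
    simulation studies and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
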