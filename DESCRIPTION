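Package: drmdetect
Title: Automated Surveillance of Drain-Related Meningitis from Routine
    Care Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for automated, model-based surveillance of
    drain-related meningitis (DRM) in patients with external
    ventricular or lumbar cerebrospinal fluid drains. Generates
    seeded synthetic multi-source hospital event data (admissions,
    drains, laboratory results, microbiology cultures, antibiotic
    starts), derives surveillance episodes and episode-level
    predictors (worst-value extraction, contamination-corrected
    cultures, empiric-therapy detection), develops a logistic
    prediction model with chained-equations multiple imputation,
    Rubin's-rule pooling, backward selection and bootstrap optimism
    correction, and evaluates it with exact binomial confidence
    intervals, ROC/calibration diagnostics and summed-probability
    group-level infection-rate estimates.
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
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
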