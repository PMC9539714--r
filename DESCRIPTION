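Package: chartscreen
Title: Symptom-Based Preschool Asthma Risk Screening (CHART) and
    Diagnostic-Accuracy Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CHILDhood Asthma Risk Tool (CHART), a
    symptom-based rule classifier that stratifies preschool children into
    high, moderate, or low asthma-risk tiers from parent-reported wheeze,
    cough, medication-use and health-care-utilization histories, together
    with the modified Asthma Predictive Index (mAPI) and
    physician-diagnosis comparators, outcome definitions at school entry
    (persistent wheeze, asthma diagnosis, health-care burden), a
    diagnostic-accuracy engine (sensitivity, specificity, predictive
    values with Wilson intervals; AUROC with DeLong or bootstrap
    intervals), and a calibrated synthetic-cohort generator so the whole
    screening pipeline can be exercised end to end without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
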