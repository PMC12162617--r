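Package: settledown
Title: Characterizing the Pre-Sleep Settling-Down Period from Wrist Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to isolate and characterize the nightly "settling down"
    period (the window between the caregiver-reported end of the bedtime
    routine and algorithmic sleep onset) from 60-second epoch wrist
    actigraphy and sleep diaries. Implements Sadeh sleep-wake scoring,
    Tudor-Locke style rest-period detection with a 30-minute diary
    reconciliation rule, rolling-window activity features (including
    Shannon entropy of activity counts), stratified cross-validated
    random-forest classification of sensory-sensitive versus non-sensitive
    children with Youden-J decision thresholds, permutation feature
    importance by AUC decrease, Mann-Whitney group comparisons, and
    standardized post-hoc regressions. A seeded synthetic cohort generator
    with a calibrated burst-mixture activity model makes the whole pipeline
    testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
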