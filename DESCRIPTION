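Package: agsurv
Title: Agricultural Injury Surveillance from Pre-Hospital Care Narratives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Case-ascertainment pipeline for occupational agricultural injuries
    in free-text pre-hospital care reports (PCRs): record cleaning (exact-match
    deduplication and removal of records of no interest), narrative
    normalization with an English Snowball (Porter2) stemmer and stemmed-keyword
    scanning with exclusion rules, categorical harmonization across state/year
    dialects, one-hot binary design matrices, a from-scratch Bernoulli Naive
    Bayes classifier with log-probability-difference variable importance,
    sensitivity-targeted posterior-threshold calibration over repeated
    train/validation splits, ROC/AUC and cross-scenario evaluation, and
    application to untagged corpora with review-sheet emission, funnel
    statistics and review-burden estimates. A synthetic PCR generator emulates
    the class-conditional keyword structure of restricted state EMS data so the
    whole system is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
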