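Package: mammorisk
Title: Hybrid Fuzzy-Statistical Breast Cancer Risk Assessment from
    BI-RADS Mammogram Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinical decision-support toolkit for breast-cancer
    screening risk. Three concurrent Mamdani fuzzy expert systems score
    the BI-RADS finding groups of a mammogram report (masses,
    calcifications, asymmetries and architectural distortion) into
    Symbolic Risks; a bagged decision-tree classifier trained on the full
    descriptor set (excluding the radiologist's BI-RADS category, with
    Min-Max age normalization and SMOTE-NC class balancing) produces a
    Statistical Risk; the risks are aggregated into a Global Risk with
    equitable weight redistribution for absent findings, corrected by an
    empirical BI-RADS-ordered weighting factor, and mapped to warning
    states with recommendations. Includes cohort readers and writers, a
    synthetic cohort generator emulating the study-design schema and
    class imbalance, classifier evaluation (sensitivity, specificity,
    MCC, AUC) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
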