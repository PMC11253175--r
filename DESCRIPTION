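Package: smecki
Title: Sex-Specific Recalibration of the MECKI Heart-Failure Prognostic Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sex-specific recalibration of the MECKI (Metabolic
    Exercise test data combined with Cardiac and Kidney Indexes) prognostic
    score for heart failure with reduced ejection fraction. Implements the
    S-MECKI logistic score with built-in female and male coefficient sets,
    synthetic cohort simulation from per-sex covariate moments, repeated
    half-split cross-validated coefficient estimation with confidence-interval
    based sex-difference classification, and evaluation of discrimination
    (Mann-Whitney AUC, DeLong test for correlated ROC curves) and calibration
    (Hosmer-Lemeshow deciles, calibration tables).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
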