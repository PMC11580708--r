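Package: copdindices
Title: Anemia-Augmented Multidimensional Prognostic Indices for COPD
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the BODEx and ADO multidimensional prognostic indices
    for chronic obstructive pulmonary disease (COPD) and their
    anemia-augmented variants (BODEx-A3, ADO-A3), which add points to the
    base score when a patient is anemic by the WHO sex-specific hemoglobin
    criteria. Provides from-scratch ROC analysis (Mann-Whitney AUC, Youden
    optimal cutpoint, DeLong's test for paired AUC comparison), a calibrated
    synthetic admission-cohort generator with a logistic mortality mechanism,
    and an end-to-end evaluation pipeline at fixed one- and three-year
    mortality horizons, including a sweep over candidate anemia weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
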