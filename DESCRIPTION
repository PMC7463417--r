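Package: pettex
Title: PET/CT Texture Analysis for Interim Response Prediction in
    Gastrointestinal Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Radiomics workflow for predicting interim chemotherapy
    response of primary gastrointestinal diffuse large B-cell lymphoma
    from pretreatment 18F-FDG PET/CT. Provides a synthetic phantom-cohort
    generator, NIfTI image/mask input-output with strict geometry
    contracts, semiquantitative PET metrics (SUVmax, metabolic tumor
    volume at a 41% threshold, ROI volume, maximal diameter), first-order
    histogram and grey-level co-occurrence matrix texture features,
    rank-based two-step feature selection, ROC analysis with Youden
    cutoffs and DeLong comparison of correlated AUCs, a combined logistic
    prediction probability with Hosmer-Lemeshow calibration, Fisher exact
    contingency analysis of clinicopathological factors, and interobserver
    agreement via the two-way random absolute-agreement intraclass
    correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
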