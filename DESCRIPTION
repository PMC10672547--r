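Package: morphosurv
Title: Tumor 3D Morphometrics and Cutoff-Stratified Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes pretreatment three-dimensional morphometrics of
    segmented tumors - volume and Wadell sphericity - from closed triangle
    meshes (STL) or binary voxel masks (NIfTI), and carries the markers
    through a prognosis analysis: ROC/Youden-index cutoff derivation,
    cutoff-stratified Kaplan-Meier and log-rank comparison, and univariate
    and multivariate Cox proportional-hazards regression. Includes a
    synthetic-data module that generates tumor-like meshes with controllable
    sphericity and patient cohorts with proportional-hazards outcomes, so
    every stage of the pipeline can be exercised and validated without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
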