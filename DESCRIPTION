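Package: ebqr
Title: Endplate Bone Quality Scoring and Cage Subsidence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the MRI-based cervical Endplate Bone Quality (EBQ)
    score and its use in predicting interbody cage subsidence after anterior
    cervical discectomy and fusion. Computes EBQ from a mid-sagittal T1-weighted
    slice and endplate/CSF annotations (3 mm subchondral band extraction,
    Schmorl-node exclusion, CSF normalisation, multi-rater reconciliation),
    classifies radiographic subsidence from segmental-height landmarks, and
    reproduces the associated cohort statistics: t-based confidence intervals,
    two-group comparisons, Pearson correlation, ROC analysis with a
    Youden-index cutoff and DeLong confidence interval, and multivariate
    logistic regression with Wald odds ratios. Includes synthetic phantom-image
    and patient-cohort generators with known ground truth so the whole pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    RNifti,
    pracma
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
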