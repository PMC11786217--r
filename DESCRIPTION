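Package: ranobm
Title: Lesion-Level Response Assessment for Brain Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lesion-level treatment-response assessment of brain
    metastases followed with serial MRI. Measures lesion size from 3D binary
    contour masks (voxel-count volume and longest axial diameter), classifies
    per-lesion response with unidimensional and volumetric RANO-BM criteria as
    well as a clinician-style previous-reference assessment, quantifies the
    stability of measurements and assessments under contour rotation and across
    time (coefficients of variation, Spearman monotonicity, response-change
    rates with Wilcoxon and McNemar tests), computes inter-method agreement
    statistics (Pearson correlation, Lin's concordance correlation coefficient,
    Cohen's kappa with and without PABAK correction, the Pearson-Filon test for
    dependent non-overlapping correlations), and evaluates how early each
    method detects the one-year response. Includes a seeded generator of
    synthetic longitudinal lesion cohorts with paired manual-style and
    automatic-style contours for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    RNifti,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
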