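Package: carpalign
Title: Automated Radiographic Assessment of Carpal Instability
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Measurement of carpal instability signs on segmented wrist
    radiographs: scapholunate joint distance, scapholunate and capitolunate
    angles, and Gilula's three carpal arcs. Bone contours extracted from
    per-bone label masks are fitted with point distribution models (PDMs,
    Procrustes-aligned PCA shape models) to locate articular facet joint
    surfaces; measurements are classified against view- and age-specific
    reference thresholds; carpal arc interruptions are detected by comparing
    observed arcs with their PDM reconstruction as a hypothetical normal
    shape (per-point z-scores, displacement vectors, and an overall
    disruption score). Includes a parametric synthetic wrist generator with
    known ground truth and the full evaluation stack (mean absolute error,
    discrete Frechet distance, Bland-Altman agreement, ROC/AUC with Youden
    operating point, stratified bootstrap, paired permutation and DeLong
    tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    png,
    tiff,
    jsonlite,
    mgcv,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
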