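Package: nodulefuse
Title: Hybrid Semi-Supervised Classification of Lung Nodule Malignancy Suspicion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for nodule-level malignancy-suspicion
    classification on LIDC-style annotations. Combines radiologist-scored
    ordinal imaging biomarkers, volumetric radiomic shape features
    (maximum axial diameter, surface area, volume) and 64-dimensional deep
    image features from a 3D convolutional network, with KNN-based
    semi-supervised pseudo-labeling of intermediate-malignancy (R3) nodules
    and a repeated-split ROC-AUC evaluation protocol. Ships a synthetic
    cohort generator so the full pipeline is testable without any imaging
    archive, a reader for LIDC-style XML contour annotations, and a compact
    Rcpp-based 3D CNN engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
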