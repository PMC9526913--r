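Package: morphopotency
Title: Morphology-Based Prediction of Serial-Passage Potency in Mesenchymal Stem Cell Clones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noninvasive prediction of the serial-passage potency of single-cell-derived
    mesenchymal stem cell clones from time-lapse phase-contrast imaging. Provides an
    eight-step segmentation pipeline for phase-contrast frames, per-cell measurement of
    twelve morphological descriptors including gray-level co-occurrence texture features,
    construction of clone-level time-course morphological profiles (descriptor x
    mean/SD x time point), LASSO and random-forest regression of potency with grouped
    leave-one-clone-out cross-validation, an exhaustive time-window by field-of-view
    data-usage sweep with bootstrap resampling, and exploratory analyses (log-area
    kernel density estimates, profile PCA, growth-rate correlation). A calibrated
    synthetic clone-cohort generator with ground-truth masks makes the full pipeline
    testable without access to raw microscope images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    glmnet,
    randomForest,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
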