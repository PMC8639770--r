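Package: focusCTA
Title: Transformed-Focus Scoring for the Bhas 42 Cell Transformation Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for scoring transformed foci in the Bhas 42 cell
    transformation assay from Giemsa-stained micrographs. Provides a seeded
    synthetic focus-image generator encoding the six OECD morphological
    criteria (basophilic, spindle-shaped, multilayered, randomly oriented,
    invasive, >= 100 cells), the classical scoring branch (discriminant-analysis
    thresholding of HSV saturation, region selection, the MD/ED/WPD shape
    features and a logistic-regression classifier), a from-scratch ResNet-18
    training and prediction harness with geometric data augmentation,
    classification metrics (confusion matrix, accuracy, recall, ROC, AUC),
    stratified data splitting, multi-trial summaries, and the assay-level
    tumour-promotion decision rule (ANOVA plus Dunnett many-to-one
    comparisons with the two-consecutive-concentrations criterion).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    multcomp,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
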