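Package: ffrepro
Title: Repeatability and Reproducibility of MRI Fat-Fraction Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing intra- and inter-reader agreement of
    bone-marrow fat-fraction (FF%) measurements from Dixon MRI. Provides a
    synthetic Dixon phantom generator with simulated reader segmentations,
    FF% map computation and intensity-scale normalization, lesion size
    classification and representative-slice selection, first-order histogram
    feature extraction, and an agreement toolkit: one-way single-measure
    intraclass correlation with exact F-based confidence intervals,
    Bland-Altman limits of agreement, within-subject standard deviation,
    Levene variance comparison between lesion size classes, bootstrap
    Spearman correlation, and reliability-study sample-size calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
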