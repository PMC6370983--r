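Package: zonegrade
Title: Zonal Biparametric MRI Texture Analysis for Prostate Cancer Grade Group Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies prostate-cancer lesions into ISUP prognostic Grade
    Groups from biparametric MRI, separately per prostatic zone (peripheral
    zone from high-b-value diffusion images; transition zone and anterior
    fibromuscular stroma from T2-weighted images). Implements 61x61-pixel
    lesion-centred ROI preprocessing (in-plane resampling, z-score
    normalization), a 38-feature panel of Galloway gray-level run-length,
    Haralick co-occurrence and first-order histogram statistics at 128 gray
    levels averaged over four directions, a k-nearest-neighbour classifier
    with per-feature z-score normalization and correlation distance, and a
    semi-exhaustive feature-subset search ranked by mean ROC AUC from
    stratified 3-fold cross-validation in a one-vs-rest design over five
    Grade Group tasks. A deterministic synthetic-cohort generator emulates
    the zonal class imbalance so the full pipeline is testable without
    clinical data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
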