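Package: piradsnet
Title: PI-RADS Knowledge-Encoded Convolutional Networks for Prostate mpMRI
    Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying clinically significant prostate cancer
    from multiparametric MRI (mpMRI) lesion patches.  Implements two 3D
    convolutional network models that fuse T2-weighted, diffusion (DWI/ADC)
    and dynamic contrast-enhanced (K-Trans) series at the decision level: a
    plain fusion model (M1) and a knowledge-encoded model (M2) whose output
    routing and composite training loss follow the PI-RADS dominant-sequence
    rules for the peripheral and transition prostate zones.  Includes the
    surrounding pipeline: findings-table and volume input, fixed-physical-size
    volume-of-interest extraction without resampling, median/min-max intensity
    normalisation, offline rotation expansion and online stochastic
    augmentation, repeated cross-validation training with SGD, AUC learning
    curves, mean-probability ensembling, per-epoch Wilcoxon model comparison,
    and a synthetic mpMRI phantom generator so the whole pipeline runs with
    no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
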