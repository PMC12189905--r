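Package: rehodyn
Title: Static and Dynamic Regional Homogeneity Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping local synchronization of resting-state BOLD
    fMRI signals via regional homogeneity (ReHo, Kendall's coefficient of
    concordance over 3x3x3 voxel neighborhoods) and its temporal variability
    (dynamic ReHo, the coefficient of variation of ReHo over sliding
    windows). Includes the surrounding analysis chain: nuisance regression
    with Friston-24 motion terms, FFT bandpass filtering, Jenkinson
    framewise-displacement motion screening, mass-univariate group GLMs with
    cluster-level inference (permutation and Gaussian random field),
    ROI-clinical correlation, and ROC/classifier evaluation. A synthetic
    cohort generator produces 4D BOLD data, motion traces and clinical
    tables with known ground truth so every stage of the pipeline can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    e1071,
    rpart,
    randomForest,
    class
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
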