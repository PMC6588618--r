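Package: dualmark
Title: Resting-State Functional Connectivity Biomarkers via Dual
    Regression and TFCE Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives mask-based resting-state functional-connectivity
    biomarkers from 4D BOLD data. Implements confound cleaning (temporal
    band-pass, Friston-24 motion expansion, CompCor), dual regression
    against a K-component spatial network template, voxelwise two-sample
    group inference with threshold-free cluster enhancement (TFCE) and
    max-statistic permutation family-wise error correction, construction
    of template (R) and group-difference (A) masks, extraction of
    mask-averaged connectivity biomarkers, and a validation battery
    (group t-tests, FDR-corrected Pearson correlations with questionnaire
    scores, ROC/AUC with a paired test for correlated AUCs). A seeded
    synthetic-cohort generator provides fully ground-truthed multi-subject
    data for calibration and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    signal,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
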