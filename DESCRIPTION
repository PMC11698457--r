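Package: mzConsensus
Title: Consensus Prediction of Bioactive Metabolites from LC-MS Feature Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-branch consensus workflow for predicting bioactive
    metabolites from an untargeted LC-MS feature table paired with bioassay
    activities (1/IC50 responses). Branch A fits a suite of NIPALS
    projection models (PCA, PLS, OPLS and their discriminant variants),
    gates them through a three-criterion validity filter (R2Y-Q2
    difference, response-permutation intercepts, CV-ANOVA) and selects
    activity-aligned features by loading rank and VIP. Branch B trains
    tree-ensemble regressors (with optional stratified bootstrap
    augmentation) and ranks features by permutation importance, Shapley
    scores and target correlation with sign screening. Each branch votes
    across its lists; the branch intersection, merged by m/z, is the final
    compound prediction. A synthetic-data generator emulating the
    five-solvent extraction design provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pheatmap
biocViews: Metabolomics, MassSpectrometry, FeatureExtraction, Regression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
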