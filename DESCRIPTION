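Package: sfelip
Title: Predicting Microalgal Lipid Extraction Profiles Under Supercritical CO2-Ethanol Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for modelling the full lipid profile recovered by
    supercritical CO2 extraction with an ethanol cosolvent. Provides
    representative-structure selection for ambiguously annotated lipids
    (K-medoids on molecular descriptors, Tanimoto fingerprint similarity,
    and activity-coefficient concordance), a 2D molecular-descriptor
    catalogue with degeneracy and Pearson-correlation pruning, a
    COSMO-SAC-type segment-activity model for infinite-dilution activity
    coefficients from sigma profiles, and a leave-one-condition-out
    regression protocol (lasso, Gaussian process, SVR, random forest,
    gradient boosting, neural network) over a factorial extraction design,
    including an IDAC ablation. A synthetic-data generator with known
    ground truth emulates the statistical shape of a microalgal lipidomic
    study for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    cluster,
    glmnet,
    ranger,
    xgboost,
    e1071,
    kernlab,
    nnet,
    yaml,
    jsonlite,
    withr,
    methods,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
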