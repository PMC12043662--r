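Package: fibrotex
Title: Texture-Based Classification of Fibrillar Collagen in SHG Microscopy Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying fibrillar collagen
    morphology in second-harmonic generation (SHG) microscopy images of
    airway tissue. Provides image preprocessing (16-to-8 bit conversion,
    low-signal filtering), extraction of 80 gray-level texture features
    from five matrix families (GLCM, GLSZM, GLRLM, GLDM, NGTDM) plus
    first-order statistics, interquartile-range outlier cleaning with
    median substitution, four feature-refinement strategies (ANOVA F-test,
    recursive feature elimination, permutation importance, interclass
    coefficient of variation), and a linear discriminant / linear support
    vector machine classifier evaluated by repeated stratified k-fold
    cross-validation and stratified holdout. A synthetic fibrillar-phantom
    generator with controllable remodeling effect size makes every stage
    testable without access to donor imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    Rcpp,
    MASS,
    e1071,
    rpart,
    randomForest,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Software
RoxygenNote: 7.3.3
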