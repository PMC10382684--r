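Package: drtrans
Title: Translating Cell-Line Drug-Response Predictors to Patient Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Supervised domain-adaptation feature selection for transferring
    drug-response classifiers trained on cancer cell lines to patient tumors
    and patient-derived xenografts. Provides a Kolmogorov-Smirnov filter that
    retains genes whose class-conditional expression distributions agree
    across domains, differential-expression/FDR prioritisation capped at
    1,000 genes, BW-ratio ranking, training protocols for logistic ridge
    regression (LogitDA) and Spearman-distance K-nearest-neighbour (KNNDA)
    classifiers with repeated stratified cross-validation, and a
    theoretically derived adjustment r/(r+1) of the prediction-probability
    cutoff for class-prior shift between domains. Includes a two-domain
    synthetic expression generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'drtrans-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'preprocess.R'
    'featureSelection.R'
    'ridge.R'
    'cv.R'
    'train.R'
    'cutoff.R'
    'evaluation.R'
    'synthetic.R'
    'pipeline.R'
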