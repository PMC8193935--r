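Package: ApparentAge
Title: Classification-Biased Apparent Brain Age for Alzheimer's Disease Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A leakage-safe pipeline that estimates an Apparent Brain Age
    (ABA) from structural-MRI morphometric feature tables and uses it, with
    chronological age, to classify Alzheimer's disease. The workflow combines
    isolation-forest outlier filtering with a Tukey-fence cutoff,
    point-biserial feature ranking with a classification-biased forward
    selection wrapper, a LASSO age regression trained on cognitively normal
    subjects only, and a logistic classifier on (age, ABA). Every prediction
    can be decomposed into per-feature scores with quartile context from the
    training data, so the linear model chain stays fully interpretable.
    Includes a synthetic cohort generator with ground truth, repeated
    stratified cross-validation, holdout and cross-cohort evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Classification, Regression, FeatureExtraction, Alzheimers
RoxygenNote: 7.3.3
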