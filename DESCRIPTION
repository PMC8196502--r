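Package: echostack
Title: Two-Step Stacked Ensemble Screening of Coronary Heart Disease
    from Speckle-Tracking Echocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening of coronary heart disease (CHD) from
    two-dimensional speckle-tracking echocardiography (2D-STE) strain
    features and clinical risk factors, using a two-level ("two-step")
    stacked ensemble of 14 base classifiers. Provides the canonical
    71-predictor feature schema over the AHA 17-segment model, CSV
    import/validation, a synthetic cohort generator with configurable
    block-correlation structure and class effects, a two-sample t-test
    feature screen, block-wise principal component reduction of the
    17-segment strain blocks, a stratified test/validation/training split
    architecture, a registry of 19 base classifier families with the
    sub-60% accuracy exclusion rule, majority and weighted voting,
    traditional one-step stacking, the two-step stacking estimator with a
    random-forest meta-learner, and a replicated evaluation harness
    reporting accuracy, sensitivity, specificity and AUC as mean and
    standard deviation over replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    class,
    e1071,
    kernlab,
    nnet,
    randomForest,
    ranger,
    glmnet,
    xgboost,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
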