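Package: curlfatigue
Title: Bicep Muscle Fatigue Detection from Wearable IMU Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for detecting bicep muscle
    fatigue during concentration-curl exercise from a wrist-worn inertial
    measurement unit (IMU) and a heart-rate monitor. Provides a synthetic
    session generator with ground-truth repetition labels, derived total
    acceleration and exerted-force signals, trough-to-trough repetition
    segmentation, fusion of Borg ratings of perceived exertion with heart
    rate into per-repetition fatigue labels, extraction of 33 windowed
    statistical features (mean, standard deviation, average absolute
    deviation over 11 signals), dual Spearman-rank feature screening with
    overlap selection, five classifier families, and subject-specific and
    leave-one-subject-out evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    pracma,
    randomForest,
    rpart,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, FeatureExtraction, TimeCourse
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'curlfatigue-package.R'
    'mlp.R'
    'models.R'
    'evaluate.R'
    'features.R'
    'generator.R'
    'label.R'
    'session-io.R'
    'select.R'
    'pipeline.R'
    'segment.R'
    'signals.R'
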