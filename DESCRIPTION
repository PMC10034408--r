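Package: cytoscreen
Title: Two-Stage Cervical Cytology Screening with Active-Learning Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a two-stage cervical cytology
    screening pipeline on single-field ThinPrep (TCT) images. Stage one
    segments and classifies cell nuclei into three classes (yin, yin-yang,
    yang) behind a pluggable detector interface with a classical
    watershed-plus-weighted-multinomial reference implementation, including
    the Mask R-CNN style loss components (RPN, weighted cross-entropy, smooth
    L1, mask binary cross-entropy) as standalone verified functions. Stage two
    aggregates per-patient cell counts into seven features and trains four
    patient-level classifiers with stratified 10-fold cross-validation. The
    package also implements the pre-label-and-revise active-learning
    annotation protocol with an annotation-cost ledger, a seeded synthetic
    cytology generator (fields, cohorts, simulated pathologist), LabelMe/COCO
    annotation interchange with a three-way augmentation scheme, and a full
    evaluation kit: IoU-matched three-class-plus-missing confusion matrices,
    sensitivity/specificity/accuracy/PPV/NPV, F1 and G-mean, rectangle-rule
    PR-curve AUC, mAP/mAR at IoU 0.5, and Friedman/Wilcoxon model comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    nnet,
    pROC,
    png,
    randomForest,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
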