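Package: fallarc
Title: Wrist-Worn IMU Fall Detection with Multi-Source Harmonization and
    Cost-Sensitive Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An activity-recognition-chain toolkit for detecting falls from
    wrist-worn inertial sensors. Provides a seeded generator of labeled
    multi-source accelerometer/gyroscope corpora; harmonization of
    heterogeneous sources (unit unification, resampling to a common rate,
    invalid-file removal, min-max normalization); sliding-window
    segmentation with majority labeling and 78 time-domain features;
    two-stage random-forest feature selection (Gini importance plus
    one-at-a-time exclusion); cost-sensitive support vector machine and
    neural network classifiers with inverse-class-frequency weights; an
    acceleration-magnitude threshold baseline; and subject-disjoint k-fold
    cross-validation with imbalance-aware metrics, including within-source,
    combined-corpus, and cross-source generalization experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
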