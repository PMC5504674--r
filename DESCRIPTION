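Package: emgcce
Title: Classification Complexity Estimation for Myoelectric Pattern Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the classification complexity of labeled
    electromyography (EMG) feature spaces before any classifier is trained.
    Implements the separability index (SI) under five Gaussian distance
    definitions (Mahalanobis, Bhattacharyya, Kullback-Leibler, Hellinger and
    a modified Mahalanobis using the pooled covariance), nearest neighbor
    separability (NNS), multiresolution purity and a repeatability index,
    each reported per movement and averaged over movements.  Around these
    estimators the package provides a complete myoelectric pattern
    recognition workbench: recording-session input/output, synthetic session
    and Gaussian cloud generators, contraction trimming and sliding-window
    segmentation, a bank of seventeen time- and frequency-domain EMG
    features, LDA/MLP/SVM classifiers in single, one-vs-one, label-power-set
    and mixed-output topologies, exhaustive complexity-driven feature-set
    selection, and rank-correlation and conflict analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    nnet,
    e1071,
    signal,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
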