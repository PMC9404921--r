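Package: ecgclr
Title: Contrastive Self-Supervised Representation Learning for Single-Lead ECG
    Stress Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a SimCLR-style contrastive self-supervised learning
    pipeline for stress and affect detection from single-lead ECG: a synthetic
    multi-subject ECG generator with condition-dependent heart-rate and
    heart-rate-variability structure, the preprocessing chain (rational
    resampling, zero-phase Chebyshev type-II high-pass baseline removal,
    per-subject z-scoring, saturation clipping, fixed-length windowing and
    SMOTE class balancing), six label-free signal augmentations and their
    ordered composition, a 1-D convolutional encoder with a softmax projection
    head trained with the normalized temperature-scaled cross-entropy
    (NT-Xent) loss, downstream fine-tuning with encoder weight transfer,
    fully-supervised and HRV-feature SVM baselines, and a repeated
    random-split evaluation protocol with test-train-ratio and augmentation
    ablation grids. The neural network forward/backward passes and the Adam
    optimizer are implemented directly on BLAS-backed matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
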