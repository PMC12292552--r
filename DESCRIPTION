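Package: supconvoice
Title: Supervised Contrastive Fine-Tuning for Speech-Based Parkinson's Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-head (classifier plus projection) training of frame-level
    speech encoders with a multi-positive supervised contrastive loss for
    detecting Parkinson's disease from voice recordings. Implements the
    single-phase training scheme in which the classification head learns on a
    gradient-detached copy of the utterance embedding while the contrastive
    loss shapes the encoder, with temperature scaling and cosine-similarity
    hard-negative up-weighting. Includes audio preprocessing (resampling,
    silence trimming, fixed-length standardization, train-only low-pass
    augmentation), MFCC and eGeMAPS baseline pipelines, speaker-independent
    stratified cross-validation with leakage guards, confusion-matrix and ROC
    metrics, Grad-CAM relevance maps over waveforms, and a synthetic
    source-filter voice cohort with controllable dysphonia effect sizes for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
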