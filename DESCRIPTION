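Package: voiceda
Title: Domain-Adversarial Deep Screening of Parkinsonian Voice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A corpus-independent screening pipeline for hypokinetic
    dysarthria in Parkinson's disease from sustained-vowel and
    diadochokinetic speech recordings. Includes a seedable multi-domain
    synthetic voice generator (source-filter vowels with controllable
    jitter, shimmer and breath noise; /pa-ta-ka/ burst trains), Mel
    spectrogram preprocessing (400 ms segments, 65 bands by 41 frames,
    z-scored), three neural feature extractors (2D-CNN, time-distributed
    CNN with bidirectional LSTM and masking, 1D-CNN with attention
    pooling) trained either as baselines or adversarially against a
    corpus detector through a gradient reversal layer, transfer-learning
    pretraining with first-layer freezing, stratified speaker-independent
    cross-validation, patient-level joint-probability decisions, and a
    corpus-invariance audit based on intra-class inter-domain Gaussian
    Kullback-Leibler divergence, trace of covariance, and t-SNE maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    Matrix,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
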