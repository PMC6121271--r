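Package: wave2vec
Title: Symbolic Encoding and Wave Embedding for Bio-Signal Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies single-channel bio-signal time series (such as 1 s EEG
    trials) by converting them into symbol sequences and embedding the symbols
    in a dense vector space. Signals are delta-encoded, quantized into a baseN
    alphabet using equal-probability bins of a fitted Gaussian with +/-2 SD
    noise clipping and a merged center bin, and the resulting sequences are
    embedded with a continuous bag-of-words (CBOW) model. Class models are the
    vector sums of training-sequence embeddings; new signals are classified by
    cosine similarity to each class model. Includes a pattern-probability
    baseline classifier, stratified k-fold cross-validation with precision/
    recall/F1 reporting, an encoding-resolution sweep harness, similarity-
    matrix visualization for identifying class-discriminating wavelet
    patterns, and a seeded generator of two-class synthetic signals with
    planted amplitude-change motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
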