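Package: neurofuse
Title: Multimodal MEG-MRI Fusion Networks for Early Alzheimer's Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying multimodal fusion of structural MRI volumes and
    resting-state MEG sensor recordings for mild cognitive impairment (MCI)
    versus healthy control classification. Implements two modality-specific
    convolutional feature extraction branches, a spatial-channel cross-attention
    fusion module (patch embedding, cross-modal attention and channel-wise
    feature aggregation), early/intermediate/late fusion strategies, a compact
    CPU neural-network engine with hand-derived backpropagation, stratified
    k-fold training and evaluation with a full confusion-matrix metric suite,
    band-wise spectral preprocessing, model complexity accounting, and a
    synthetic cohort generator that emulates the shapes and group structure of
    a two-site MEG+MRI dementia cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    rhdf5,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
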