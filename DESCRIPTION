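Package: attnEEG
Title: Multi-Level EEG Attention-State Classification with Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for four-level attention-state recognition from
    multichannel EEG: synthetic cohort generation with controlled band-power
    structure, FIR band-pass preprocessing with automated bad-segment
    rejection, sliding-window segmentation, extraction of ten per-channel
    features (six time-domain statistics, sample entropy, and wavelet-packet
    theta/alpha/beta band-energy ratios), four feature-selection strategies
    including a sequential-forward-selection wrapper, RBF-kernel support
    vector machine classification with pooled and cross-session subject-level
    protocols, and paired before/after statistical comparison. Published
    step-accuracy and per-subject accuracy tables ship as replayable fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
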