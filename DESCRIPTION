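Package: cogmap
Title: Temporally Discounted Cognitive-Map Estimation from Sequence Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
                  role = c("aut", "cre"))
Description: Tools for analysing probabilistic sequence-learning experiments in
    which stimuli are drawn from random walks on latent graphs. Estimates each
    learner's temporally discounted internal map of the transition structure
    from reaction-time residuals (a single-parameter maximum-entropy learner),
    locates recording channels whose evoked-activity geometry matches that map
    using cross-validated Euclidean representational similarity analysis with
    circular-shift permutation nulls, characterises module separability of
    low-dimensional embeddings, and tracks the time course of map formation in
    sliding windows. Includes channel-quality metrics and interictal-discharge
    detection for intracranial recordings, and synthetic-data generators that
    emulate the full design for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    e1071,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
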