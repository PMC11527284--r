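Package: stresslens
Title: Stress Feature Extraction and Profiling from Social-Media Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for detecting and profiling psychological stress in
    short social-media posts. Couples contextual token embeddings with
    latent Dirichlet allocation fitted by collapsed Gibbs sampling to build
    topic-fused document representations, stratifies a corpus by a logistic
    sentiment head into a negative "stress" document set, tags gender,
    degree-level and institution mentions with a from-scratch peephole
    BiLSTM-CRF sequence labeller (Viterbi decoding, forward-algorithm
    likelihood), and aggregates extracted facets into multi-dimensional
    stress profiles. Ships seeded synthetic-corpus generators with planted
    ground truth so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
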