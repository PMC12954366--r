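Package: emodecode
Title: Time-Resolved EEG Decoding of Emotional Expressions Within and
    Across Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate decoding of emotional facial expressions from
    multichannel EEG epochs. Implements per-timepoint linear discriminant
    analysis under leave-one-participant-out and bidirectional
    cross-dataset schemes, region-of-interest and spatio-temporal
    searchlight decoding, cluster-based sign-flip permutation statistics,
    interval-null Jeffreys-Zellner-Siow Bayes factors, and decoding
    onset/peak latency estimation. A synthetic two-experiment ERP
    generator with a controllable shared emotion-discriminative component
    makes every stage of the pipeline verifiable without access to raw
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
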