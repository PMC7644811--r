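Package: synlab
Title: Muscle Synergy Extraction and Motor Primitive Analysis for Locomotor EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the modular analysis of locomotor electromyography:
    linear-envelope preprocessing and gait-cycle time normalization of
    multi-channel EMG, muscle synergy extraction by non-negative matrix
    factorization with multiplicative updates and linear-fit factorization
    rank selection, functional classification of motor primitives into
    fundamental and combined synergies, motor primitive geometrics (circular
    center of activity, full width at half maximum, half-maximum heat maps),
    rescaled-range Hurst exponent estimation, gait spatiotemporal parameter
    variability, and scalar plus one-dimensional permutation statistics for
    comparing locomotion conditions. Includes a synthetic trial generator
    (ground-truth synergies, gait events, fractional Gaussian noise) so the
    whole pipeline is testable without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    car,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
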