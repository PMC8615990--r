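Package: erpdecode
Title: Time-Resolved Multivariate Decoding of Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of two-condition event-related potential
    (ERP) studies with a go/no-go priming structure. Provides a forward
    simulator for multi-subject EEG (toy spherical head model, 1/f background
    noise, injectable condition effects), standard preprocessing (zero-phase
    Butterworth band-pass, common average reference, epoching, baseline
    correction, peak-to-peak artifact rejection), time-resolved single-trial
    decoding with a shrinkage-regularized linear discriminant classifier under
    leave-one-subject-out cross-validation, permutation-based significance of
    the accuracy time course with extraction of contiguous significant
    intervals, channel-space paired t-test topographies within those
    intervals, and an eLORETA-style distributed inverse solution for signed
    condition-difference source maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
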