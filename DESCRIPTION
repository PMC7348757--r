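Package: earesn
Title: Attention-State Classification from In-Ear EEG with Echo State Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates labeled two-channel in-ear EEG sessions from a visual
    vigilance protocol, extracts standardized band-wise spectral and temporal
    features on 0.5 s epochs, classifies attentive versus resting states with a
    leaky echo state network whose linear readout is trained by ridge
    (Tikhonov) regression, smooths readout traces with a causal moving
    average, and evaluates classifiers under within-subject (leave-one-run-out),
    cross-subject (leave-one-subject-out) and pooled k-fold cross-validation
    with grid-search optimization of the leaking rate and spectral radius.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
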