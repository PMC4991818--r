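Package: ecogcoupling
Title: Cortico-Cortical Amplitude and Phase Coupling in ECoG Brain-Computer Interface Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cortico-cortical interactions in
    electrocorticographic (ECoG) brain-computer interface (BCI) sessions.
    Implements short-time windowed covariance (STWC) maps of lagged
    amplitude-amplitude coupling between high-gamma envelopes, bi-phase
    locking value (bPLV) maps of cross-frequency quadratic phase coupling,
    Morlet-wavelet phase estimation, high-gamma onset detection and
    response-locked trial realignment, surrogate-data max-statistic
    inference (phase-randomized and trial-shuffled nulls), behavioral
    chance bounds, motor screening, and skill-acquisition comparisons.
    Includes a synthetic ECoG session generator with ground-truth injected
    coupling so the whole pipeline is testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
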