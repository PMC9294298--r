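Package: capfreq
Title: Frequency-Specific Coactivation Pattern Analysis of Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Frame-wise coactivation pattern (CAP) analysis of resting-state
    ROI time series resolved by frequency band. Decomposes BOLD signals into
    the typical low-frequency range and the slow-5 to slow-2 sub-bands,
    clusters individual frames into recurring whole-brain states, aligns
    state sets across bands with the Hungarian algorithm, quantifies state
    dynamics (fraction of time, persistence, counts, transition
    probabilities, resilience), runs the associated group and frequency
    statistics, and classifies diagnostic status from CAP spatial features
    with F-score feature selection and a linear support vector machine.
    Includes a synthetic-cohort generator with known ground truth so every
    stage is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    clue,
    cluster,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
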