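Package: emdecode
Title: Masking Empirical Mode Decomposition and Time-Resolved Decoding of
    Epoched MEG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing epoched magnetoencephalography (and other
    multichannel electrophysiology) data with the Hilbert-Huang approach:
    masking empirical mode decomposition of single-channel signals into
    intrinsic mode functions, Hilbert spectral characterisation of each mode
    (instantaneous frequency and amplitude, marginal energy spectra, dominant
    frequencies), time-resolved two-condition decoding with cross-validated
    ROC AUC, group-level cluster-based sign-flip permutation inference, and a
    simplified L2 minimum-norm inverse with dSPM noise normalisation and
    region-of-interest extraction. A bundled simulator generates sensor-space
    mixtures of narrow-band evoked cortical sources through a toy lead field,
    including a three-source delta/theta benchmark cohort used throughout the
    test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
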