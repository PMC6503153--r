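Package: alphadrift
Title: Time-on-Task Drift Analysis of EEG Alpha Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying slow, systematic drifts in the frequency
    and power of alpha-band (8-13 Hz) oscillations across an EEG recording
    session. Implements split-half FFT analysis of trial baselines,
    instantaneous alpha-frequency estimation from the Hilbert phase
    derivative with a median-filter bank, single-trial time-on-task trend
    statistics with spatio-temporal cluster-based permutation correction,
    histogram-based trial stratification for dissociating frequency and
    power drifts, and ICA-based separation of alpha sources with circular
    statistics on their joint power/frequency trends. Includes a synthetic
    EEG generator with planted non-stationarities so every stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    ica,
    boot,
    matrixStats,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
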