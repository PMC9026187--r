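Package: alphanft
Title: Closed-Loop Alpha Neurofeedback Simulation and EEG Analysis Pipeline
Version: 0.1.0
Authors@R: person("alphanft", "developers", role = c("aut", "cre"),
    email = "alphanft@example.org")
Description: Simulates a closed-loop alpha relative-power neurofeedback
    (NFT) experiment on a cohort of virtual EEG subjects and provides the
    full pre/post evaluation pipeline: multitaper spectral estimation,
    individual alpha frequency (IAF) detection, IAF-anchored band powers
    and relative power, event-related desynchronization (ERD), an online
    sliding-window feedback engine with a dynamic reward threshold,
    CSP + RBF-SVM motor-imagery decoding with stratified cross-validation,
    sensor-space functional connectivity (phase lag index and imaginary
    coherence), and the paired-t / Pearson / Benjamini-Hochberg statistics
    used to summarise training effects. Includes an EDF+ reader/writer for
    interchange with standard EEG tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
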