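Package: cueloop
Title: Closed-Loop EEG Neurofeedback Simulation and MVPA Decoding of
    Smoking Cue Reactivity
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and testing individualized, multivariate
    pattern analysis (MVPA) based closed-loop EEG neurofeedback pipelines
    for nicotine cue reactivity.  Provides a synthetic-EEG generator and a
    virtual subject so the complete protocol (offline classifier
    construction from a block-design cue-reactivity task, then real-time
    feedback with an adaptive 11-level picture mapping) can be exercised
    end to end without human data.  Includes EDF input/output with a
    sidecar event table, epoching with baseline correction, high-pass
    filtering (zero-phase offline and causal online), recursive
    least-squares removal of ocular artifacts, amplitude-threshold epoch
    rejection, Morlet-wavelet band power, cluster-mass permutation feature
    selection with family-wise error control, a linear support vector
    machine with Platt probability calibration, stratified leakage-safe
    cross-validation, a virtual-clock feedback session engine with trace
    logging, and evaluation statistics (ERP grand averages, split-half
    signal-to-noise ratio at Pz, score-versus-cycle regression, normality
    and one-sample t tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    matrixStats,
    stats,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
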