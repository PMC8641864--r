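Package: pingwm
Title: Decoding and Network Simulation Toolkit for Working-Memory Pinging EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how task-irrelevant "pinging" impulses affect the
    decodability of working-memory content from multichannel EEG. Provides a
    phenomenological generator of synthetic EEG trials (Gamma-shaped evoked
    waveforms with trial-varying parameters, lead-field projection to scalp
    channels, and an impulse-window reduction in noise variability), epoch-level
    preprocessing (baselining and its reversal by epoch stitching, detrending,
    Gaussian smoothing, Hilbert alpha-band power), time-resolved Mahalanobis
    representational-dissimilarity decoding of circular stimulus labels
    summarized as vector strength with shuffle-null calibration, statistical
    power tools (windowed one-sided tests, trial/session subsampling grids,
    bootstrap intervals, randomization tests, a cross-validated median split of
    sessions with a shuffle predictor), across-trial variance analyses
    (percent change from baseline, decoding-split variance differences, outlier
    session screening), and a spiking ring-network simulator of leaky
    integrate-and-fire neurons contrasting an activity-silent regime with
    short-term synaptic plasticity against a bump-attractor regime without it,
    with Fano-factor, tuning, and reactivation readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
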