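Package: trimanus
Title: Offline Simulation and Analysis of Hybrid Gaze-EEG-Manual Control
Version: 0.1.0
Author: Trimanus Developers
Maintainer: Trimanus Developers <trimanus@example.org>
Description: Reproducible, hardware-free re-implementation of a "tri-manual"
    virtual-reality control stack: two tracked hands plus a third virtual hand
    driven by gaze targeting and single-channel EEG attention. Provides seeded
    synthetic multimodal session streams (512 Hz EEG, 120 Hz gaze, 90 Hz
    controller poses), the full attention-decoding pipeline (artifact gating,
    Butterworth band-pass, Welch band powers, baseline-normalised beta/(alpha+
    theta) metric), a three-tier false-trigger mitigation cascade, Kalman gaze
    filtering with cone targeting, softmax control-authority arbitration,
    Matern-3/2 Gaussian-process workload prediction with adaptive
    interventions, a kinematic task simulator, and evaluation utilities for
    trial metrics and paired statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
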