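Package: ppgscreen
Title: Hypertension Screening from Photoplethysmography with an
    Attention-Augmented LSTM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for screening hypertension from
    single-channel photoplethysmography (PPG) recordings. Provides a
    synthetic PPG cohort generator with per-beat ground truth, Butterworth
    plus trough-anchored cubic-spline preprocessing for baseline-wander
    removal, pulse-wave fiducial detection (systolic peak, dicrotic notch,
    dicrotic wave) and a 20-dimensional time/frequency feature set, an
    LSTM classifier with Bahdanau-style attention pooling trained by
    backpropagation (implemented natively, with plain LSTM, bidirectional
    LSTM, support-vector-machine and k-nearest-neighbour baselines), and
    evaluation protocols covering held-out windows, robustness to
    unpreprocessed inputs, and leave-subjects-out reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    class,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
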