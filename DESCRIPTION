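Package: semgkit
Title: Surface EMG Hand-Posture Recognition, Simulation and Variability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multichannel surface electromyography (sEMG) hand-posture
    recognition and biofeedback research. Provides zero-phase Butterworth band-pass
    conditioning and windowing of multichannel recordings, the Hudgins time-domain
    feature set (mean absolute value, waveform length, zero crossings and slope sign
    changes) with rest-calibrated noise thresholds, session-wise ten-fold
    cross-testing of a multilayer-perceptron posture classifier with confusion-matrix
    reporting, cluster-variability analysis via Mahalanobis-distance silhouettes and
    t-SNE embeddings, radar-plot activation targets with a pattern-match score, and a
    seeded synthetic sEMG generator that emulates multi-day training protocols with a
    tunable trial-to-trial variability schedule, spectral shaping and inter-channel
    crosstalk, so the full pipeline runs without human recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    nnet,
    jsonlite,
    Rtsne,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
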