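Package: oddballerp
Title: Simulation and Analysis of Audio-Visual Oddball EEG Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing event-related potential (ERP)
    experiments in which rare audio-visual deviant stimuli (an exploding and a
    burning box in a virtual industrial scene) are embedded in a stream of
    standard trials. Provides a parametric synthetic-session generator
    (24-channel 10-20 montage, evoked component templates, 1/f background,
    alpha rhythm, line noise, drift and ocular artifacts), a deterministic
    preprocessing pipeline (zero-phase FIR filtering, epoching, baseline
    correction, ocular-artifact removal, variance/kurtosis trial rejection,
    subject and grand averaging), ERP peak measurement with Welch's t-test
    comparisons, single-trial feature extraction (windowed variance, Welch
    power spectral density, Daubechies-8 discrete wavelet transform, and their
    fusion), and linear support-vector-machine detection of deviant events
    with cross-validated accuracy, sensitivity and specificity reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
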