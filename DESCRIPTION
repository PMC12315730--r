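Package: smrloop
Title: Closed-Loop Sensorimotor-Rhythm Neurofeedback Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for sensorimotor-rhythm (SMR)
    event-related desynchronization (ERD) neurofeedback experiments. Provides a
    synthetic-data module that generates multichannel EEG with a state-dependent
    mu-band oscillator, EMG reaction-time traces, and motor-evoked-potential
    (MEP) sweeps with known ground truth; a causal online scoring chain (large
    Laplacian, Butterworth/notch filtering, sliding Hanning-window power
    spectral density, the ERD feedback formula, yoked-sham replay); spectral
    calibration of individual alpha/beta bands; offline event-related spectral
    perturbation (ERSP) evaluation; EMG burst-onset reaction-time extraction;
    short-interval intracortical inhibition (SICI) quantification; and the group
    statistical layer (mixed repeated-measures ANOVA with sphericity correction,
    effect sizes, partial correlations, false-discovery-rate adjustment, and
    a-priori sample-size computation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
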