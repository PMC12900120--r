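Package: pwvlab
Title: Pulse Wave Velocity Estimation on an In Vitro Vascular Phantom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating arterial-phantom stiffness and pulse wave
    velocity (PWV) from two-site pulse waveforms. Provides a synthetic-waveform
    generator emulating a factorial pump/vessel experiment (stroke volume,
    heart rate, wall thickness, Shore A hardness), zero-phase signal
    conditioning, derivative-based fiducial-point detection, per-beat feature
    extraction, hardness estimation by ordinary least squares and by a
    first-order Sugeno adaptive neuro-fuzzy inference system (ANFIS) trained
    with hybrid least-squares/gradient learning, Shore-A-to-Young's-modulus
    conversion under five published elastomer models, Moens-Korteweg PWV
    computation, foot-to-foot reference transit-time estimation, and the
    associated validation statistics and ordinal classification benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    pracma,
    jsonlite,
    nnet,
    e1071,
    class,
    randomForest,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
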