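Package: gaitcast
Title: Forecasting Lower-Limb Gait Kinematics with Encoder-Decoder LSTM Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Short-horizon forecasting of lower-limb kinematic time series
    (thigh and shank linear acceleration and angular velocity, the signals a
    body-mounted inertial measurement unit reports) with an encoder-decoder
    long short-term memory (LSTM) network. Provides a synthetic multi-subject
    gait generator with stride-locked harmonic waveforms, the standard
    biomechanics signal conditioning chain (zero-phase low-pass filtering,
    z-score normalisation, numerical differentiation), a sliding-window
    transformation to a supervised sequence-to-sequence problem, a compiled
    LSTM trainer (Adam, mean-absolute-error loss) with a pure-R peephole LSTM
    reference cell, and an evaluation harness reporting per-feature MAE, MSE
    and correlation for first-window and whole-stride scopes, including
    input-window sweeps and forecast-horizon comparisons under
    leave-one-subject-out splits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
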