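Package: fatiguetrack
Title: Online Muscle Fatigue Tracking from Surface EMG and Accelerometer
    Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tracks localized and overall muscular fatigue during exercise
    from wearable sensor recordings. Each muscle contributes one surface
    electromyogram (sEMG) channel and a tri-axial accelerometer. The
    pipeline low-pass filters and resamples the channels, decides from the
    acceleration autocovariance whether the movement is periodic
    (contraction-recovery) or sustained, extracts and concatenates the
    active sEMG during periodic work, estimates the moving-window spectral
    mean frequency, tracks its decline online with forgetting-factor
    recursive least squares, converts the tracked slope to a localized
    fatigue level, and fuses muscles into one overall fatigue trajectory
    with gradient-normalized weights. A seeded synthetic-signal module
    generates sEMG-like noise with a prescribed mean-frequency slope and
    periodic or sustained acceleration traces so that every stage is
    testable without recorded data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
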