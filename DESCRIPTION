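Package: tympanomatch
Title: Sender-Receiver Matching Between Lizard Distress Calls and Tympanic Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the match between acoustic signals and
    peripheral auditory sensitivity in lizards that emit distress calls.
    Provides parametric synthesis of harmonic and noisy calls and of pure-tone
    stimulus schedules, spectro-temporal call feature extraction (duration,
    time to maximum amplitude, fundamental and dominant frequency, harmonic
    counts, ultrasound flags, frequency-modulation patterns), the laser
    Doppler vibrometry analysis chain (replicate signal-to-noise filtering,
    averaging, FFT velocity estimation, velocity transfer functions, best
    frequency and half-maximum sensitivity range), a zero-lag spectral
    cross-correlation statistic for call-eardrum matching, a resonant-eardrum
    simulator for fully synthetic experiments, and population-comparison
    statistics (chi-square, t tests, stepwise two-group linear discriminant
    analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
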