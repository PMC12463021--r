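Package: oscillogic
Title: Oscillation Statistics and Boolean Logic from Multichannel
    Bioelectric Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing slow electrical oscillations recorded from
    biological cultures on multichannel data loggers, and for evaluating
    Boolean logic gates built on top of them.  Models each channel as a
    damped sinusoid, generates synthetic multichannel recordings with
    Gaussian noise and baseline drift, extracts per-channel oscillation
    statistics (period, amplitude, frequency, power) by threshold-and-
    prominence peak detection, binarizes signals at fixed or half-amplitude
    thresholds, evaluates the seven standard Boolean gates sample-wise with
    high-state frequencies and noise-induced error rates, and computes
    cross-channel Pearson correlation matrices.  Includes presets for a
    coccolithophore microalga culture and an algae-proteinoid mixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
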