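Package: ecgcwt
Title: Spline-Wavelet QRS Detection and Ambulatory ECG Record Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reimplementation of the computational core of a
    three-lead ambulatory (Holter) ECG monitor: a streaming QRS-complex
    detector based on the continuous wavelet transform with B-spline
    wavelets at integer scales, beat-to-beat RR-interval and heart-rate
    output, the monitor's 15-byte-per-sample binary record format with
    24-bit ADC code conversion, closed-form device arithmetic (full scale,
    resolution, storage, battery life) with a real-time alarm engine, a
    synthetic three-lead ECG generator with known beat ground truth, and
    validation statistics (sensitivity, positive predictivity,
    Bland-Altman agreement, lag-aligned correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
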