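Package: p300wd
Title: Wide-and-Deep P300 Detection for Matrix Speller Brain-Computer
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for single-trial P300 detection in matrix-speller
    brain-computer interfaces. Simulates the oddball speller paradigm
    (6 x 7 character grid, 13 row/column flashes per sequence) with
    subject-heterogeneous multichannel EEG, runs the standard
    event-related-potential preprocessing chain (montage selection,
    Butterworth bandpass, epoching, baseline correction,
    amplitude-threshold artifact rejection, decimation), and trains a
    hybrid detector that combines a wide logistic-regression branch over
    dense EEG plus crossed one-hot participant features with a deep
    one-dimensional convolutional branch, optimized per coordinate with
    the FTRL-Proximal online algorithm. Includes within-subject,
    leave-one-subject-out and split-half evaluation harnesses, online
    sliding-window prediction, and speller character decoding. Reads and
    writes EDF+ recordings and a portable gzip-compressed JSON epoch
    container.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
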