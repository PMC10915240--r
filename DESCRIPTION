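Package: ecscbf
Title: Electromagnetic Coupling Sensing Analysis of Pulsatile Cerebral Blood Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for resonant-frequency (RF) traces
    produced by electromagnetic-coupling sensors monitoring pulsatile cerebral
    blood flow. Provides a forward equivalent-circuit model that doubles as a
    synthetic-data generator for phantom and two-state volunteer scenarios,
    wavelet threshold denoising and pulse-amplitude analysis (including the
    change ratio of amplitude, CRA), conversion of windowed traces into
    grayscale waveform images, extraction of Hu-moment, gray-level
    co-occurrence matrix, histogram-of-oriented-gradients and local binary
    pattern image features with fixed dimensional layout, importance-threshold
    feature selection, and a grid-search train/evaluate harness for
    classifying overall blood-flow level between physiological states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    ranger,
    e1071,
    png,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    class,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
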