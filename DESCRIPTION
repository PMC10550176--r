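Package: surroundscope
Title: In-Silico Neurophysiology of Surround Effects in Convolutional Networks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-silico electrophysiology toolkit for characterizing
    contextual surround effects in feedforward convolutional networks.
    Computes theoretical receptive-field geometry (size, jump, center
    displacement) from the kernel/stride recursion, runs grating-based
    size and orientation tuning protocols (grating summation field,
    suppression index, surround-suppression tuning, center-surround
    orientation interactions), performs a two-step gradient visualization
    of the most facilitative center and the most suppressive or
    facilitative surround under a 1/f spectral parameterization with
    jitter regularization, quantifies center-surround similarity (color
    and reference-feature correlations), fits subtractive versus divisive
    surround gain models, and compares surround suppression for
    naturalistic textures against spectrally matched noise. Ships fully
    analytic fixture networks (conceptual two-pathway model, oriented
    toy convolutional model, center-surround Gabor units) so every
    protocol is testable without trained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
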