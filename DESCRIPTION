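Package: pscdetect
Title: Detection and Supervised Classification of Spontaneous Synaptic Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and classifying spontaneous postsynaptic
    currents (and similar unitary events) in single-channel time-series
    recordings. Candidate events are detected by FFT-based deconvolution of
    the recording against a peak-scaled biexponential template, thresholded
    on the noise of the resulting detector trace, and then screened either
    by Pearson correlation against the template or by a random-forest
    classifier trained on a ten-feature description of each candidate.
    Includes a ground-truth simulator of synaptic-like waveforms with
    log-normal amplitude and kinetics, ROC-style accuracy evaluation against
    simulated ground truth, Matthews-correlation agreement between raters,
    and an exact paired permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    minpack.lm,
    randomForest,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
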