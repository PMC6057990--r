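Package: slipcode
Title: Slip-Based Texture Coding Analysis for Whisker Vibrotactile Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize 3D texture surfaces (height, slope,
    angularity, spatial autocorrelation and spectra), to extract local
    (stick-slip event based) and global (best-frequency and intensity)
    coding variables from whisker angular-position traces, to quantify
    pairwise texture discriminability via the area under the ROC curve,
    and to compare coding variables with perceptually blurred one-against-all
    classifier analyses. Includes a synthetic-data generator that emulates
    sandpaper surfaces and constant-speed whisker sweeps with stochastic
    slip transients, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    pracma,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
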