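Package: rampfold
Title: Force-Ramp Analysis for Single-Molecule Protein Unfolding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of optical-trap force-ramp experiments on
    modular proteins such as the inner-ear tip-link cadherin PCDH15. Provides a
    saturation-plus-linear-spring force-extension model with series-spring and
    contour-length calculus, a stochastic Bell-Evans unfolding simulator with
    ground-truth event logs, change-point detection of discrete unfolding steps,
    segment-wise model fitting with a fixed enthalpic stiffness, clustering of
    trajectories into conformational states with k-nearest-neighbour assignment,
    interstate transition maps, and refolding and stiffness statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    mclust,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
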