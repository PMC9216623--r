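Package: stripeflow
Title: Stripe Formation Analysis for Crossing Pedestrian Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes the striped patterns that emerge when two
    groups of pedestrians cross at an angle. Implements an edge-cutting algorithm
    that tracks which intra-group bonds are severed by opposing walkers and
    identifies stripes as the residual clusters, a pattern-matching technique that
    fits a two-dimensional parametric sinusoid (Gabor-style) to pedestrian
    positions to estimate global stripe orientation and wavelength, rotating-
    calipers minimum bounding boxes for per-stripe width and orientation, and a
    synthetic crossing-flow trajectory generator with known ground truth for
    validating the whole pipeline. Includes trajectory I/O, zero-phase Butterworth
    gait filtering, crossing-angle and bisector-frame estimation, and per-trial
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    minpack.lm,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
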