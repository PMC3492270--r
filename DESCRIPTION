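Package: spiderwalk
Title: Trajectory Tracking and Path Analysis for Nocturnal Spider Learning Walks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for measuring burrow departure paths of a
    nocturnal wandering spider from infrared video: background-subtraction blob
    tracking (batchwise temporal-mean differencing, spatiotemporal connected
    components, volume/shape selection), planar checkerboard calibration
    (normalized DLT homography estimation with optional radial distortion),
    automated outlier flagging and constant-acceleration Kalman smoothing,
    sinusoidal path-shape descriptors (regression-axis crossings, per-cycle
    wavelengths and amplitudes), excursion summaries and departure-rate fits,
    Rayleigh speed-distribution fitting, body-to-burrow alignment angles with
    an azimuthal eye visual-field compass, circular summaries with bootstrap
    confidence intervals, and one-way PERMANOVA on Bray-Curtis dissimilarities
    of fourth-root-transformed path descriptors. A synthetic-scene generator
    renders ground-truth sinusoidal departures to noisy vignetted image stacks
    so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
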