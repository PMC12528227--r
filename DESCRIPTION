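Package: specfuse
Title: Multi-Technique Spectroscopic Reaction Monitoring with
    Heterocovariance Mapping, Kinetic MCR-ALS and Data Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric workflow for inline/online reaction monitoring by
    near-infrared, Raman and low-field proton NMR spectroscopy. Provides a
    synthetic multi-technique spectral generator with bilinear kinetic
    structure, per-technique preprocessing (Savitzky-Golay smoothing,
    iterative-polynomial and asymmetric-least-squares baseline correction,
    peak normalization, chemical-shift referencing, region selection),
    synchronous two-dimensional heterocovariance spectroscopy, evolving
    factor analysis, multivariate curve resolution by alternating least
    squares with non-negativity (FNNLS) and hard kinetic-model constraints,
    PCA-based qualitative monitoring, PLS and support-vector-regression
    calibration, and low-level and mid-level multi-block data fusion with
    RMSEC/RMSEP metrics and F-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    Matrix,
    e1071,
    deSolve,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
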