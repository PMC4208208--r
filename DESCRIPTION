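Package: sescom
Title: Subject-Specific Whole-Body Center-of-Mass Estimation via the
    Statically Equivalent Serial Chain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the three-dimensional whole-body center of mass (CoM)
    of a human subject from segment orientations alone, after a short
    calibration against center-of-pressure (CoP) measurements. The body is
    modelled as a nine-segment rigid chain; the statically equivalent serial
    chain (SESC) reduces its mass distribution to a seven-parameter vector
    that is identified by linear least squares from static postures. Includes
    identification-quality diagnostics (condition number, parameter relative
    standard deviations, k-ratios, significance t-tests), sensor-stream
    preprocessing (resampling, zero-phase Butterworth filtering, static-window
    detection, skeleton-to-orientation conversion), a Winter
    anthropometric-table comparator, a virtual-subject simulator emulating
    marker-based and depth-camera measurement noise, and a cross-validation
    evaluation protocol.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
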