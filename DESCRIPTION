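Package: uvcled
Title: UV-C LED Disinfection Kinetics and Single-Cell Damage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for UV-C LED water-disinfection experiments on
    indicator bacteria. Computes log reductions and fluence-based inactivation
    rate constants from plate-count survival curves (linear fits over the
    initial fluence range and origin-constrained quadratic fits capturing
    tailing), inverts rate constants into required-fluence tables for target
    log reductions, quantifies photoreactivation and dark-repair recovery,
    segments fluorescence-microscopy images of stained cells and computes
    per-cell intensity statistics including the skewness of DAPI-stained
    nucleoids as a metric of UV-induced DNA reorganization, classifies
    PI-positive membrane-compromised cells, and calibrates CPD ELISA standard
    curves with inverse prediction. Includes synthetic-data generators for
    survival curves with Poisson plate counts, multi-channel microscopy scenes
    with ground-truth masks, and ELISA standards, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
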