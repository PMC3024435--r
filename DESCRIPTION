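Package: fcois
Title: Functional Connectivity Analysis of Optical Intrinsic Signal Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts multi-wavelength optical intrinsic-signal reflectance
    movies of the mouse cortex into oxy- and deoxy-hemoglobin time series via
    Modified Beer-Lambert spectroscopy, computes resting-state functional
    connectivity (seed correlation maps, full pixel-by-pixel correlation
    matrices and their singular value decomposition), parcellates the cortex
    into functional regions with an iterative winner-take-all correlation
    algorithm followed by hierarchical clustering, and registers a named
    polygon atlas with a two-landmark similarity transform. A synthetic
    phantom generator with planted network structure provides ground truth
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml,
    grDevices,
    graphics
Suggests:
    ape,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
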