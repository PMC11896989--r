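Package: chlorotex
Title: Leaf Chlorophyll Estimation from Hyperspectral Canopy Images by
    Spectral-Textural Feature Combination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate leaf chlorophyll content (SPAD units) of
    banana canopies from hyperspectral image cubes. Implements NDVI-based
    vegetation/soil segmentation, a registry of 20 chlorophyll-sensitive
    vegetation indices (original and red-edge forms), principal-component
    transformation of the cube with eight Haralick texture features computed
    in sliding 3x3 gray-level co-occurrence windows, Pearson and maximal
    information coefficient feature screening, an exhaustive two-pair
    vegetation-index x texture-feature combination search (ratio, normalized
    difference, and difference forms) ranked by linear fit, multivariable
    regression (PLSR, adaptive regression splines, SVR, Gaussian process
    regression) under 10-fold cross-validation, a red-edge band sweep,
    SPAD-to-extracted-chlorophyll calibration, and per-pixel chlorophyll
    mapping. Includes a seeded synthetic canopy scene generator with known
    per-pixel chlorophyll so the full pipeline is testable without field data,
    and readers/writers for ENVI and TIFF hyperspectral cubes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    tiff,
    e1071,
    mixOmics,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
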