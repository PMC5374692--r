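Package: tasselmorph
Title: Image-Based Phenotyping of Maize Tassel Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measures morphological traits of maize tassels from paired
    background/sample photographs taken in a field photography booth.
    From each image pair the package derives a quality-controlled binary
    mask (background subtraction, automatic thresholding, largest-component
    filtering), skeletonizes the mask, extracts the geodesic main path from
    the tassel base to the spike tip, and computes tassel length (line
    integral of a smoothing spline), branch number (concentric-circle
    intersection counting), tortuosity, area, compactness, box-counting
    fractal dimension, skeleton length, and perimeter. Downstream tools
    estimate trait repeatability from variance components, correlations of
    genotype means, and the coefficient of variation of the root mean
    squared error against hand measurements. A seeded synthetic-tassel
    generator with exact geometric ground truth supports validation of
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    lme4,
    Rcpp,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
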