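Package: vesseg
Title: Automated 3D Segmentation and Morphometry of Synaptic Vesicles in
    Electron Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects, segments and measures synaptic vesicles in 3D electron
    tomogram stacks. The pipeline rescales stacks to 1 nm/pixel, enhances
    contrast and denoises, separates the electron-lucent vesicle lumina from
    the membranous background by per-slice mean thresholding inside an
    interpolated hand-traced cell boundary, splits touching candidates with a
    distance-transform watershed (2D then seeded 3D), and characterizes every
    candidate (volume, Feret diameter, fitted-ellipsoid diameters, sphericity,
    elongation, nearest-neighbour distances) with organism-specific exclusion
    criteria and an inner-to-outer membrane diameter correction. Ships a
    synthetic phantom generator with ground truth, a precision/recall
    evaluation harness, and a four-stage command line interface (simulate,
    register, measure, evaluate). Reads and writes MRC (modes 0/1/2) and
    uncompressed multi-page grayscale TIFF stacks plus plain-text polygon ROI
    files and CSV result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
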