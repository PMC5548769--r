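Package: ossict
Title: Synchrotron Micro-CT Simulation and Bone Morphometry of Meniscal Ossicles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic micro-CT pipeline for quantifying
    bone erosion at meniscal ossicles, the small sesamoid bones of the rodent
    knee meniscus. Provides an ossicle phantom generator with programmable
    stochastic surface erosion and analytically known ground truth, a
    propagation-based phase-contrast forward model (parallel beam, flat/dark
    fields, Poisson noise, 360-degree extended field of view), preprocessing
    and reconstruction (flat-field correction, sinogram stitching,
    single-distance phase retrieval, filtered back projection), segmentation
    (3D median filter, Otsu auto-threshold, 6-connected labeling), standard
    bone morphometry (BV/TV, BS/BV, BS/TV via surface triangulation and hole
    filling), and Welch two-sample group statistics, together with TIFF/YAML/CSV
    input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
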