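Package: crpen
Title: Penetration Modeling for Chemical Reactivation of Resin-Embedded
    Fluorophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the penetration of alkaline buffer into resin-embedded
    specimens during chemical reactivation (CR) of quenched fluorophores
    (GFP, FITC). Implements the semi-infinite one-dimensional diffusion
    solution of Fick's second law with a fluorescence saturation coefficient,
    extraction of normalized depth profiles and isointensity contours from
    time series of 3-D image stacks, joint estimation of the diffusion
    coefficient D and saturation coefficient K from two contour slopes,
    forward prediction of CR-thickness-versus-time curves, and a synthetic
    z-stack generator for validation without confocal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
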