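Package: voxcensus
Title: Quantification of Expanded Whole-Organism Light-Sheet Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Volumetric quantification toolkit for expanded, cleared
    whole-organism fluorescence volumes: multiscale Hessian blob ("ball")
    and tube ("rod") enhancement, watershed instance segmentation for
    nuclei and neuron censuses, whole-body morphometry (length, volume,
    isosurface area and dimensionless shape ratios), cylinder-correlation
    muscle-fiber tracing with orientation classification, allometric
    scaling fits with optional breakpoints, and a seeded synthetic phantom
    generator providing exact ground truth for every pipeline stage.
    Physical voxel spacing and linear expansion factors are carried
    through all measurements so results can be reported at expanded or
    biological scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
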