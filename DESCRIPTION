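Package: trapquant
Title: Automated Image-Based Quantification of Extracellular Traps and
    Cell Death
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An automated image-cytometry pipeline that quantifies
    extracellular trap formation (ETosis) and non-ETotic cell death
    simultaneously from two-channel fluorescence micrographs of
    Hoechst- and SytoxGreen-stained invertebrate immune cells. Provides
    tile-based focus scoring for image quality control, block-based
    illumination correction, global robust-background thresholding with
    shape-based declumping of touching nuclei, per-object intensity
    measurement, FlowJo-style bivariate gating into live, ETotic and
    dead populations, and replicate-aware two-sample comparisons of
    population percentages. Includes a synthetic scene generator with
    ground-truth labels so every stage of the pipeline can be validated
    without access to live-cell imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
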