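Package: fiberpom
Title: Non-Destructive Tensile Strength Prediction for Protein Fibers from
    Paired Brightfield and Polarized-Light Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated image analysis of paired brightfield and polarized
    optical microscopy (POM) micrographs of individual protein fibers, such as
    wet-spun recombinant spider-silk fibers. Segments the fiber in the
    brightfield frame (Yen entropy or fixed threshold), measures the local
    diameter everywhere along the fiber with the Euclidean distance transform
    sampled on the medial axis, quantifies birefringence as POM intensity over
    the fiber region including bright-segment decomposition, and calibrates a
    linear model that predicts engineering tensile strength from the
    diameter-normalized POM intensity. Includes engineering stress-strain
    analysis of force-displacement records, a ground-truthed synthetic
    micrograph generator for validation, and a batch pipeline with CSV/JSON
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
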