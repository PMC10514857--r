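Package: scratchquant
Title: Standardized Quantification of Scratch-Assay Wound Closure from
    Microscopy Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Texture-based segmentation and quantification of the cell-free
    wound region in scratch (wound-healing) assay microscopy images.
    Detects the scratch band from local intensity texture, subtracts
    migrated-cell islands, measures center-line wound width and wound area
    per field of view, aggregates multiple fields of view into per-replicate
    total scratch areas, computes percent-wound-remaining-open kinetics with
    replicate summaries, and plans how many fields of view are needed to
    cover at least 76 percent of the scratched length. Includes a synthetic
    scratch-scene generator with exact ground-truth masks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Segmentation
RoxygenNote: 7.3.3
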