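Package: vesselmorph
Title: Microvessel Morphometry from CD31-Stained Brightfield Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects blood vessels in CD31/DAB immunohistochemistry images,
    closes open endothelial outlines, and measures a per-vessel morphometric
    descriptor suite (area, length, width, perimeter, aspect, roundness,
    perimeter ratio, deformity, Hu-moment shape factor, branching). Vessels
    are classified into microvascular segments (capillaries, post-capillaries
    and metarterioles, sinusoids, venules and arterioles, veins and arteries)
    by caliber, and per-sample quantity statistics (density per square
    millimetre, stained-area percentage, relative density and stained area
    per segment) are summarised. Includes a calibrated synthetic phantom
    generator with per-vessel ground truth for validation, and a batch
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
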