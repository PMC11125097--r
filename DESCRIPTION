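Package: fluorloc
Title: Multi-View Fluorescence Localization of Crop Seedlings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects systemic-fluorescence signals of dye-marked crop
    seedlings in single-channel chamber images and recovers the plant
    center from a five-view (overhead plus four inclined mirrors) imaging
    geometry. Implements threshold segmentation with sub-pixel blob
    centroiding, a six-region frame partition with a sixteen-case
    occlusion-scenario dispatcher, closed-form mirror-geometry solvers for
    the opposite-pair and two-frame single-mirror cases, a seeded synthetic
    scene simulator of the imaging rig, and a success-radius evaluation
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
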