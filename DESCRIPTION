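Package: psidots
Title: Dot Extraction from Porous Silicon Microarray Reflected-Light Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts measurement dots from reflected-light images of porous
    silicon (PSi) microarrays. Implements a three-stage pipeline: HSV-based
    dual-channel (saturation + value) Otsu binarization with morphological
    cleanup, tilt estimation by a minimum-bounding-rectangle (MBR)
    principal-axis search followed by rotation correction, and equidistant-grid
    spot segmentation with per-dot mean-gray quantification. Includes a
    seedable synthetic image generator that renders tilted grids of irregular
    near-circular cells with known ground truth, so every stage can be
    validated without proprietary chip images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
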