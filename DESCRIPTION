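Package: rhizopan
Title: Minirhizotron Tube Imaging: Acquisition Planning and 360-Degree
    Panorama Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated minirhizotron root imaging with a rotating
    in-tube camera. Plans 360-degree scan geometry (snaps per rotation,
    strip counts, overlap), sizes the off-grid power system (per-cycle
    energy, battery and solar panel capacity) and estimates wireless
    transfer time. Reconstructs the unwrapped tube panorama from
    overlapping snaps: radial (barrel) distortion calibration and
    correction, hue-plane specular reflection removal, exposure and
    color normalization, overlap cropping, and translational strip and
    panorama stitching with closure-error distribution. A synthetic
    cylinder-scene simulator renders degraded snaps with known ground
    truth so the whole chain is testable without field hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
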