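Package: heartnc
Title: Navigator-Channel Adaptation for Reconstructing 3D Heart Volumes
    from 2D Planning Radiographs
Version: 0.1.0
Authors@R:
    person("heartnc", "developers", email = "heartnc@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct patient-specific three-dimensional heart
    volumes from two-dimensional planar radiotherapy planning images.
    Implements population heart-model construction from binary organ masks,
    reference/test patient matching by thorax measurements, digitally
    reconstructed radiograph (DRR) projection, navigator-channel edge-shift
    detection via second-derivative inflection points, linear/bilinear
    adaptation of population-to-reference deformation fields, and Dice
    volume-overlap evaluation. Ships a deterministic thorax/heart phantom
    generator so the full pipeline can be exercised end-to-end with known
    ground truth, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
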