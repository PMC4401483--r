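Package: slitfundus
Title: Slit-Lamp Fundus Videography Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric-optics modelling and image analysis for fundus
    examination with the slit lamp and hand-held converging lenses.
    Provides the lens-power to fundus-magnification model with calibrated
    on-retina metrology, simulation of the slit-lamp aperture plate and
    curtain slit, surface-contour reconstruction from oblique slit-beam
    deflection (the optic section applied to the retina), sharpness-based
    still-frame selection from fundus video, rigid registration with
    flicker-test change detection, mosaic stitching of gaze-directed
    fundus tiles, spherical-cap coverage estimation for panretinal
    documentation schemes, and a deterministic synthetic fundus generator
    (vessel tree, height maps, oblique slit renderings, tile sets, change
    pairs, jittered video) supplying ground truth for every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
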