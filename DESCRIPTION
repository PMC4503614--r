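Package: laserquad
Title: Seafloor Area, Camera Pose and Altitude from Paired Laser Lines in
    Oblique Underwater Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Photogrammetric scaling of oblique seafloor still images using
    the classical rig of two parallel sheet lasers fixed to an ROV frame.
    From seven pixel measurements of the projected laser lines in a single
    image, the package estimates the ground length and area of the
    laser-delimited trapezoid, the camera's height above the seabed, its pan
    and tilt angles via the vanishing point of the laser lines, and the
    seabed slope when an external tilt reading is available. First-order
    maximal (absolute-sum) uncertainties are propagated for every estimate.
    Includes an exact pinhole forward model used as a simulation oracle, a
    synthetic still-image renderer, a sub-pixel green-laser-line detector,
    annotation file handling, an equal-ground-area grid overlay, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
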