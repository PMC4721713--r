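Package: pupilglint
Title: Pupil and Glint Center Detection in Near-Infrared Eye Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detection of the pupil center and corneal-reflection (glint)
    centers in single-channel near-infrared eye images, as used by pupil
    center-corneal reflection (PCCR) gaze trackers. Implements three-class
    optimal thresholding (trimodal Otsu), morphological cleanup with
    threshold-scaled structuring elements, projection-based rough pupil
    localization, circular ring rays location (CRRL) boundary detection
    with gradient-amplitude interference elimination and subpixel spline
    refinement, constrained total-least-squares ellipse fitting with a
    self-contained Jacobi eigensolver, and glint center estimation by
    log-linearized 2-D Gaussian fitting. Includes a seeded synthetic
    eye-image renderer with exact ground truth, batch evaluation
    (stability and RMS error), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
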