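Package: helistripe
Title: Simultaneous CT Overbeaming and Overranging Measurement from Helical Stripe Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computed-tomography dose quality assurance using a single
    helical acquisition recorded on a cylindrical computed-radiography plate.
    The unwrapped plate shows one tilted stripe per gantry rotation; the full
    width at half maximum of a profile perpendicular to a stripe, magnified to
    the rotation centre, gives the actual beam width (overbeaming and dose
    efficiency), while the full width at tenth maximum of the longitudinal
    mean profile gives the actual exposure length (overranging). Includes a
    physics-based forward simulator of stripe images -- helical source motion,
    trapezoidal z-aperture with focal-spot penumbra, entrance-surface exposure
    accumulation on the cylinder, dynamic z-collimator tapering, and
    logarithmic pixel-value encoding -- so the entire analysis pipeline can be
    exercised and validated without a physical scanner or plate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
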