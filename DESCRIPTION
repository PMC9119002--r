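Package: polarasm
Title: Polar Angular Spectrum Beamforming for Curvilinear Ultrasound Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and Fourier-domain beamforming for curvilinear
    (convex) ultrasound transducer arrays. Implements the angular spectrum
    method in polar coordinates, with a closed-form radial propagator for
    wavefield extrapolation between concentric shells, and builds a
    shot-profile migration beamformer on top of it: transmit wavefields are
    forward-propagated, receive channel data are back-propagated, and the two
    are cross-correlated at every image point. Also provides a time-domain
    point-source reference simulator, synthetic speckle/lesion/point-target
    phantoms, a virtual-source synthetic-aperture delay-and-sum baseline, and
    image-quality metrics (NRMSE, lateral resolution, lesion contrast) so the
    beamformers can be compared quantitatively on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
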