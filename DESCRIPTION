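Package: rmoct
Title: Reflection-Matrix Optical Coherence Tomography Simulation and
    Wavefront Shaping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying deep-tissue light delivery with
    reflection-matrix optical coherence tomography (RM-OCT).  The package
    simulates coherent light propagation through layered random-phase-screen
    phantoms calibrated in scattering mean free paths, assembles scanning
    reflection matrices, performs the time-reversal (singular value)
    decomposition with Tikhonov filter-factor calibration and
    deviation-criterion selection of the regularization parameter, computes
    the model energy matrix that maps the internal energy distribution per
    scan point, separates single- from multiple-scattering photon classes by
    singular-value thresholding, and derives matched incident wavefronts by
    regularized matrix inversion for phase-only wavefront shaping.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
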