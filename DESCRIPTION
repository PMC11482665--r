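Package: pocketscope
Title: Computational Methods for Pocket-Scale In Situ Microscopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-independent implementations of the image-analysis and
    optical-design computations used by low-cost microcontroller-based
    microscopes: finite-conjugate optics calculations (magnification,
    numerical aperture, diffraction limit, sampling margins), compression-
    and DCT-based sharpness metrics with focus-stack autofocus and extended
    depth-of-field compositing, exposure/focus bracketing planning and
    best-frame selection, inline (lensless) hologram simulation and
    angular-spectrum refocusing, diffraction-grating spectrum extraction
    with pixel-to-wavelength calibration, and timelapse analytics
    (flat-field correction, phase-correlation drift tracking, variance
    projection, intensity time series). Seeded synthetic-data generators
    emulate the imaging physics of such devices for testing, and a thin
    command-line interface exposes every operation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    jpeg,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
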