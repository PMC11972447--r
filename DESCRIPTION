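Package: apcmicro
Title: Adaptive Phase Contrast Microscopy Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of adaptive phase contrast microscopy for
    microtiter plates. Detects the misalignment between the condenser annulus
    and the phase ring in Bertrand-lens pupil images using classical computer
    vision (downscaling, CLAHE, thresholding, contour roundness filtering and
    an approximate mean-square ellipse fit), maps the detected offset to a
    corrective LCD annulus position through a linear calibration model, and
    quantifies the relative phase-contrast area of full-well images with a
    relative-threshold plus morphology pipeline. A seeded synthetic-optics
    simulator emulates the meniscus-induced annulus displacement so that every
    stage can be exercised and benchmarked without microscope hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
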