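Package: cranioguide
Title: Facial-Landmark-Guided 10-20 Head Landmark Construction and Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates subject cranial fiducials (nasion, inion, preauricular
    points, vertex) from camera-space facial landmarks through a precomputed
    multi-view linear mapping, constructs labeled 10-20/10-10/10-5 head-surface
    layouts on triangular meshes, registers atlas layouts onto individual
    subjects by affine fitting, and stabilizes landmark streams across video
    frames with a moving-average filter.  Ships a synthetic head-population
    generator (parametric ellipsoid meshes with ground-truth cranial and facial
    landmarks and a nine-view camera grid) together with a cross-validation
    harness for landmark-error reporting, so the whole pipeline is testable
    without any licensed head-scan library.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
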