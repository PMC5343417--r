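Package: radiusSSM
Title: Statistical Shape Modelling and Morphometrics of the Distal Radius
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for population-level statistical shape
    analysis of distal-radius surface models: triangulated mesh handling and
    validation, rigid registration (iterative closest point) and generalized
    Procrustes alignment, dense template-projection correspondence, a Point
    Distribution Model (principal-component shape model) with an
    explained-variance mode count, anatomical landmark detection (radial
    styloid, dorsal tubercle), standardized cross-sectional cut planes with
    morphometric parameters (maximum width, maximum depth, perimeter, area),
    group statistics, and leave-one-out random-forest classification of side
    and gender from shape coefficients. Includes a calibrated synthetic
    distal-radius generator so the whole pipeline is testable without
    clinical imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    nortest,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
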