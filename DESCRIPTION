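Package: depthfall
Title: Fall Detection from Depth-Camera Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects falls of a single person from sequences of depth images
    (millimetre-resolution range maps such as those produced by structured-light
    depth cameras). Implements per-pixel single-Gaussian background modelling
    with adaptive updates, silhouette extraction, ellipse-based head
    localization via a foreground coefficient, dense spatio-temporal context
    (STC) head tracking with frequency-domain learning, least-squares floor
    plane estimation from a user-designated region, and an adaptive two-stage
    head/centroid height decision rule. Includes a synthetic depth-scene
    simulator with analytic ground truth so the whole pipeline can be exercised
    and validated without a physical sensor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    mgcv,
    stats,
    tibble,
    ggplot2,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
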