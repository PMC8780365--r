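Package: crowdwatch
Title: Privacy-Preserving Social Distance Estimation and Crowd Monitoring
    from Pose Detections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates pedestrian ground positions from 25-joint pose
    detections, maps them to real-world top-view coordinates through a
    ground-plane homography, smooths and tracks them with a quality-flag
    adaptive Kalman filter and a global-nearest-neighbor tracker, and
    derives social-distance violations, occupancy and crowd density maps,
    overcrowding regions, and a full evaluation metric suite. Includes a
    synthetic surveillance-scene simulator (constant-velocity pedestrians,
    articulated stick figures, pinhole projection, occlusion and pixel
    noise) so every stage is testable without video data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
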