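Package: gsigait
Title: Gait Skeleton Image Templates for Skeleton-Based Gait Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 3D skeletal joint sequences from heterogeneous pose
    sources (Kinect-v2, MediaPipe) into a unified 17-keypoint body model,
    rigidly normalizes viewpoint and translation in homogeneous coordinates,
    projects orthographically onto a fixed 80x120 canvas, and rasterizes the
    motion into compact grayscale gait templates: line-based and joint-based
    Gait Skeleton Images (GSI) plus the classical Gait Energy Image (GEI)
    baseline. Includes a parametric walking simulator with identity, viewpoint
    and covariate (bag/coat) structure, gait-cycle segmentation, a compact
    convolutional network for identification, leave-one-trial-out and
    gallery/probe rank-1 evaluation protocols, and cross-view report
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
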