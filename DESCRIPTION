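Package: gazeqc
Title: Data-Quality and Latency Assessment for Head-Mounted Eye Trackers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for assessing the data quality of eye trackers embedded
    in virtual-reality head-mounted displays. Provides a spatial pipeline
    (angular accuracy, root-mean-square sample-to-sample precision, bivariate
    contour ellipse area, data-loss percentage, head-motion phase
    segmentation from HMD quaternions, and row-wise group statistics over a
    5 x 5 fixation-target grid) and a video-based end-to-end latency
    estimator (HSV colour-mask event detection, pixel-count flagging, onset
    pairing, and median frame counting). Includes synthetic generators for
    gaze logs and frame sequences with known ground truth, used to validate
    every stage of both pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
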