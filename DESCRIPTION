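Package: duotrack
Title: Tracking-by-Detection for Dual Robotic Microsurgical Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Data-association tracker for up to two robotic microsurgical
    instruments observed as per-frame 2D bounding-box detections with
    confidence scores. Implements confidence and position filtering of raw
    detections, left/right identity assignment, IoU-based matching with
    IoU-weighted box smoothing, constant-velocity Kalman gap filling with
    edge-exit rules, re-tracking of instruments that leave and re-enter the
    field of view, CLEAR-MOT style evaluation metrics (MOTA, MOTP, and the
    mean sum of consecutive area variation, MSCAV), a synthetic
    detection-stream simulator for testing without video, and file/CLI
    plumbing for MOT-style CSV streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
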