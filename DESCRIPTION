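Package: cowfuse
Title: Multi-View Cattle Behavior Recognition by IoU Association and
    Decision-Level Ensemble Fusion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing pipeline for multi-camera cattle behavior
    monitoring aimed at estrus detection. Consumes per-frame object
    detections (cow identity boxes and behavior boxes) from two
    synchronized views of a pen, links each cow to a behavior by
    bounding-box Intersection-over-Union with previous-frame fallback,
    resolves cross-view disagreements with a rule-based decision-level
    ensemble, and scores the resulting behavior timelines against ground
    truth with an estrus/non-estrus binarization. Includes a synthetic
    two-view detection-stream simulator with view-specific
    misclassification modes so the whole pipeline is testable without
    video or detector weights, plus readers and writers for YOLO-format
    detection files, JSON-lines streams, and CSV timelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
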