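Package: loosenrate
Title: Tobacco Leaf Loosening-Rate Detection from Stem/Bunch Object Detections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns object-detector output from conveyor-belt tobacco leaf
    loosening lines into per-bunch loosening rates and qualified/unqualified
    verdicts. A bunch of leaves is qualified when the number x of single-stem
    detections overlapping its bounding box stays below an operator-set
    maximum lambda; the loosening rate is lambda/x x 100%. The package
    provides the axis-aligned box geometry and the IoU-family bounding-box
    regression losses (CIoU, WIoU v1/v2, GIoU, DIoU, EIoU, Focal-EIoU) used
    by modern single-stage detectors, the fast-normalized weighted fusion
    arithmetic of bidirectional feature pyramids, bunch-level evaluation
    metrics (precision, recall, F1, average precision) with a
    confidence-threshold sweep to pick the operating point, a synthetic
    conveyor-scene generator with a detector-noise model for network-free
    benchmarking, and readers/writers for YOLO-format labels and
    corner-format detection records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
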