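Package: leukofuse
Title: Confidence-Weighted Ensemble Fusion and Evaluation for Leukocyte Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses bounding-box predictions from multiple leukocyte detectors
    into a single ensemble output by greedy IoU clustering, a majority-support
    discard rule, majority-vote typing, and confidence-weighted box averaging.
    Includes a full detection-evaluation stage (101-point interpolated average
    precision, mAP and mAR over IoU 0.50:0.95, per-class AP, precision-recall
    curves, detection confusion matrices, and interference-factor-conditional
    accuracy), readers and writers for COCO JSON and Pascal VOC XML annotation
    formats, and a seeded synthetic benchmark generator that emulates blood-smear
    scenes and noisy detectors so the whole pipeline is testable without images
    or trained networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
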