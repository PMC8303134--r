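Package: grafscreen
Title: Graf-Method Hip Ultrasound Screening Pipeline with Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated Graf-method screening of developmental
    dysplasia of the hip (DDH) from coronal hip ultrasound images. Implements
    a two-stage multi-detection pipeline (structure segmentation, white-on-black
    stage-1 conversion, landmark keypoint extraction), Graf alpha/beta angle
    geometry with an iliac-wing check angle for image appropriateness gating,
    inter-rater agreement statistics (percent agreement, positive percent
    agreement, Cohen's kappa, two-way absolute-agreement ICC with Cicchetti
    interpretation bands, paired-difference summaries), a synthetic
    ultrasound phantom generator with exact ground truth for end-to-end
    testing, a compact trainable two-stage detector, and file-format plumbing
    (PNG, DICOM conversion with anonymization, CVAT-dialect annotation XML,
    paired-reading CSV) behind a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
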