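Package: periostage
Title: Radiographic Periodontitis Staging, Rater Agreement and Phantom
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for staging periodontitis from landmark measurements on
    dental panoramic radiographs. Computes percentage alveolar bone loss from
    cemento-enamel junction, bone-crest and root-apex landmarks with the 2 mm
    biologic-width correction, assigns Stage I-IV per the 2018 classification
    (bone-loss bands and remaining-teeth rule), and evaluates agreement between
    raters with binary diagnostic metrics, exact binomial confidence intervals,
    linearly weighted Cohen's kappa, and mAP50-style detection scoring. Includes
    image enhancement operators (unsharp masking, histogram equalization, 3x3
    Gaussian smoothing), kappa-based sample-size planning for two-rater
    agreement studies, annotation format converters (polygon JSON and
    YOLO-style normalized segmentation text), dataset splitting, and a phantom
    generator producing landmark cohorts with known stages, synthetic
    radiograph-like images with ground-truth masks, and simulated rater pairs,
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
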