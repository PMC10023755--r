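Package: pwmltools
Title: Composite-Image Synthesis and Detection Evaluation for Punctate
    White Matter Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds copy-paste composite training corpora for punctate white
    matter lesion (PWML) detection in infant brain MRI slices and scores
    detector output against ground truth. Provides a synthetic brain-slice
    phantom with known tissue maps and injectable punctate lesions, percentile
    intensity normalization, lesion-patch extraction with inclusion/exclusion
    rules, anatomically constrained patch pasting, the standard geometric
    augmentation set with consistent bounding-box geometry, Pascal VOC and
    YOLO annotation I/O, a deterministic multiscale blob detector, and an
    evaluation stack with threshold-swept sensitivity/PPV, false-positive
    anatomical localization, Mann-Whitney score comparison and average
    precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
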