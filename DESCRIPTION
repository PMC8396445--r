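Package: stickypest
Title: Saliency-Map Detection and Counting of Insect Pests on Sticky Traps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and counts small insect pests on yellow sticky-trap
    images. Region proposals are generated from a frequency-tuned saliency
    map (CIELAB distance to the mean image colour after Gaussian blurring),
    gated by an area filter and a background-foreground classifier, and
    refined with tune-up boxes around each activation-region centroid.
    Patch classifiers are pluggable; a lightweight convolutional network
    trained with adaptive moment estimation is included. Redundant
    detections are removed by an improved non-maximum suppression that
    first merges overlapping same-class boxes (boosting their confidence)
    before conventional suppression and a confidence cut-off. Includes a
    dual-path fusion rule for combining an external detector's boxes, the
    full detection and counting evaluation protocol (detection rate, false
    detection rate, F1, MAE, MSE), PASCAL VOC annotation input/output, and
    a seeded synthetic sticky-trap scene generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    farver,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
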