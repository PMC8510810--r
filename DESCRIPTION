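Package: mitodetect
Title: Two-Phase Mitosis Detection with a Wavelet U-Shaped Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects mitotic figures in H&E breast histopathology tiles from
    weak centre-point labels. Phase one trains a U-shaped fully convolutional
    segmentation network whose down- and up-sampling operators are the
    discrete wavelet transform and its inverse; thresholded probability maps
    yield minimum circumscribed rectangles that, combined with the weak
    labels, become bounding-box strong labels. Phase two trains an
    R-CNN-style detector (region proposals, CNN features on warped crops,
    linear-SVM classification, ridge bounding-box regression) on those
    boxes. Includes the contest-style 8-micrometer centre-distance
    evaluation protocol, a seeded synthetic tile generator, file-format
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    generics,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    png,
    igraph,
    e1071,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
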