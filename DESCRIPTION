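Package: aquaweight
Title: Non-Intrusive Fish Weight Estimation from Underwater Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating the weight of farmed fish (Tilapia) from
    single-camera underwater images in turbid water. Implements frame
    sampling and a turbid-water image enhancement chain (sharpening, colour
    correction matrix, exposure adjustment), detection utilities (bounding
    box to size extraction, score filtering, IoU and COCO-style average
    precision, detector loss functions) with pluggable detector backends,
    and a three-stage regression cascade that estimates camera-to-fish
    depth, converts pixel dimensions to centimetres, and predicts weight
    using linear, random forest, or support vector regression with grid
    search model selection. Includes seven area-based allometric weight
    estimators for comparison, evaluation metrics, a synthetic fish
    cohort/scene generator with ground truth for end-to-end testing, and
    readers/writers for VIA-style annotation JSON and tabular results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    randomForest,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    openxlsx
Config/testthat/edition: 3
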