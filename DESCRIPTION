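Package: herdcount
Title: Tiled Detection and Evaluation of Large Mammals in Drone Orthomosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for counting large mammals (caribou adults, calves, and
    mosaicking "ghosts") in large drone orthomosaics. Provides overlap-aware
    tiling of mosaics with unique annotation ownership, bounding-box
    annotation file I/O, greedy IoU-based matching of detection sets against
    a reference observer, detection evaluation metrics (accuracy, precision,
    recall without true negatives, percentage difference, missing and
    misclassification proportions, per-tile Pearson correlation), pooling of
    multiple observers, a synthetic scene generator with configurable
    observer/detector error models, and a simple contrast-based baseline
    detector so the full tile-detect-merge-evaluate pipeline runs end to end
    without a trained neural network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
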