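Package: handmotion
Title: Automatic Hand-Movement Detection from Pose-Estimation Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects hand and arm movements in video-derived pose keypoint
    time series. Per frame and per keypoint, thresholded sliding-window tests
    classify rest versus movement; detected movements are extended to the next
    rest state, merged across a default set of eight manual keypoints,
    post-processed (short-segment removal, gap merging) and exported as
    time-stamped annotations importable into ELAN or ANVIL. Includes a reader
    for per-frame pose-estimator JSON output (25 body + 2 x 21 hand keypoints),
    keypoint CSV round-tripping, a seeded synthetic trajectory generator with
    ground-truth movement segments, and an agreement evaluator based on
    temporal-overlap segment matching and frame-wise raw agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
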