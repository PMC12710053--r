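Package: radlen
Title: Automated Radicle Length Measurement from Seed Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the radicle (embryonic root) length of germinating seeds
    from RGB images. Implements a prompt-driven coarse-to-fine segmentation
    pipeline over a pluggable promptable-segmenter contract, a Gaussian
    chromaticity model that separates each seed mask into seed coat and
    radicle, skeletonization with a weighted skeleton graph whose geodesic
    distances yield the radicle pixel length, and pixel-to-millimetre
    calibration from a reference object of known physical area. Ships a
    seeded synthetic scene generator with exact ground truth and an oracle
    segmenter backend so every stage is testable without pretrained models,
    together with standard segmentation evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
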