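Package: spinemark
Title: Two-Stage Landmark Detection for Lateral Lumbar Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects vertebral centers and corner landmarks of the lumbar
    vertebrae (L1-L5) and the upper end plate of S1 in lateral lumbar
    radiographs. The first stage regresses per-vertebra center confidence
    maps with a wide-kernel encoder-decoder trained under random spine
    cutout augmentation, and repairs shifted center sets with a gap-statistic
    test and a band-masked channel-sum algorithm. The second stage crops each
    vertebra with spacing-derived square windows and localizes corner
    landmarks with coordinate-channel convolutions and scalar part affinity
    fields. Includes a synthetic spine phantom generator with exact ground
    truth, a compact CPU convolutional-network engine with analytic
    backpropagation, evaluation metrics (pixel and relative distance errors
    with outlier accounting), and an end-to-end experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
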