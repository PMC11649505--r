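Package: hyperseg
Title: Hybrid CNN-Transformer Segmentation of Microscopic Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of microscopic hyperspectral image (MHSI)
    cubes with a hybrid convolutional/transformer encoder-decoder network.
    Implements multi-scale token division with mirror padding and gated token
    fusion, a spatial-channel fusion transformer block (multi-head spatial and
    channel attention, dense connections, cross-attention fusion), a decoder
    built on modulated deformable convolutions, a compound Dice plus
    cross-entropy loss, PCA spectral-band reduction, hyperspectral cube and
    label-mask input/output (ENVI, multi-page TIFF, RDS container, PGM), a
    seeded synthetic-cube generator with linear endmember mixing, and a
    five-fold cross-validation training harness, all in base R with a small
    built-in reverse-mode automatic-differentiation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
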