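Package: nucseg
Title: Nucleus Instance Segmentation Post-Processing, Evaluation and
    Whole-Slide Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning the two output heads of a nucleus
    segmentation network (a nuclear-material probability map and a
    nuclear-center detection map) into instance-level segmentations of
    H&E histopathology patches, exporting them as polygon contour CSV
    files, and validating them at scale. Includes marker-controlled
    watershed instance separation, Reinhard-style stain normalization,
    whole-slide tiling bookkeeping, the patch-level evaluation suite
    (Dice with nuclei-count weighting, Instance-Dice, object
    precision/recall, Pearson count correlation, MAE%), a two-level
    whole-slide quality-control engine (random region checking, quality
    grouping, statistical outlier selection), and a synthetic H&E patch
    generator with exact instance ground truth and controllable
    corruption so every stage is testable without real slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
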