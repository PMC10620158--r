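Package: epiwound
Title: Quantification of Epithelial Wound-Healing Assays from Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for quantifying in-vivo epithelial wound-healing
    experiments: cortical-actin accumulation from line intensity profiles
    (baseline correction, width-constrained peak detection, margin-normalized
    edge ratios, line/wound/animal aggregation), dye-uptake scoring as
    particles per nucleus, nuclear transcription positivity from paired
    channels, and wound-closure kinetics as percent-of-original-area curves
    with per-timepoint group statistics. Seeded synthetic-image and
    time-series generators with exact ground truth make every stage of the
    pipeline verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
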