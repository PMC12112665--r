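Package: painface
Title: Weighted Facial-Expression Analysis for Pain Level Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates pain intensity from facial landmarks using Facial Action
    Coding System (FACS) action-unit (AU) zones. Computes per-zone landmark
    displacements between a neutral and an activated frame, calibrates them to
    0-5 AU intensities, scores pain with the Prkachin-Solomon pain intensity
    (PSPI) formula and a six-zone maximum-activation formula, classifies the
    facial expression from AU intensities, and applies per-emotion weights
    (0.8-1.7) to produce an emotion-weighted pain score with a six-level
    categorization. Includes image preprocessing (resize, unsharp mask,
    contrast/brightness, pixel scaling), canonical landmark alignment, a
    synthetic face-mesh generator with known ground truth, and an evaluation
    harness (confusion matrices, precision/recall/F1/AUC/mAP, pain-level
    accuracy tables, temporal pain profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
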