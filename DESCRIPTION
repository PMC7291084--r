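Package: orgscreen
Title: Organelle Morphology and Membrane-Carrier Dynamics in Image-Based RNAi Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies organelle morphology and membrane-carrier dynamics in
    high-content fluorescence microscopy screens. Provides a synthetic-scene
    generator with known ground truth, nuclei-seeded cell segmentation and
    per-cell fragment detection, the Golgi polar distribution score (an
    angular-histogram statistic of organelle dispersion), per-cell organelle
    count/intensity/area metrics, preprocessing, detection, tracking and
    classification of transport carriers in time-lapse videos, and screen-level
    normalization to negative controls with nonparametric and parametric
    group testing. All results are returned as tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
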