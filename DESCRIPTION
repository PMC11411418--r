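Package: chromanose
Title: Colorimetric Sensor-Array Analysis for Volatile Metabolite Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paper-based 12-spot colorimetric sensor
    arrays (optoelectronic noses) that fingerprint volatile organic compounds
    and urinary metabolites through RGB difference maps. Covers synthetic
    response and scan-image generation, spot registration and mean-color
    extraction from before/after scans, the corrected 36-feature response
    vector and its Euclidean-norm summary, discriminant-ability-function (DAF)
    optimization of assay conditions, PCA / Ward hierarchical clustering /
    PCA-LDA discrimination with confusion-matrix reporting, and a clinical
    layer with spirometry-based severity grading, severity-response
    regression, age correlation and replicate reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    jsonlite,
    ggplot2,
    MASS,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
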