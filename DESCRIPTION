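Package: ecosens
Title: Vegetation Sensitivity and Memory-Effect Mapping from Monthly Raster Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pipeline for mapping the sensitivity of vegetation cover to
    climate variability from monthly NDVI, air-temperature, precipitation and
    land-surface-temperature raster stacks. Implements per-pixel Mann-Kendall
    significance and Theil-Sen slope trend mapping on annual composites, the
    temperature-vegetation dryness index (TVDI) via dry/wet-edge fitting in
    NDVI-LST space, DCT-based penalized-least-squares gap filling with
    generalized cross-validation, monthly detrending and z-score
    standardization, lag-1 autoregressive regression of NDVI anomalies on
    climate anomalies (vegetation memory), principal-components-regression
    climate weights, mean-variance-residual variability scores, and the
    0-100 vegetation sensitivity index that combines them. A seeded synthetic
    scene generator with known ground-truth structure makes every stage
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    withr,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
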