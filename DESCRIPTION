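Package: radscreen
Title: Analysis of High-Throughput Radiation-Susceptibility Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for cell-based high-throughput radiation
    susceptibility screens read out by automated counting of fluorescently
    stained nuclei. Converts laser-scan object lists to per-well cell counts
    with a size-threshold single/cluster classification, computes surviving
    fractions and fits the linear-quadratic dose-response model, removes
    plate, session and screen technical effects from log2 counts by a joint
    linear model that preserves the irradiation effect, calls radiosensitizer
    hits from per-siRNA treatment-by-silencing interaction tests with
    Benjamini-Hochberg false discovery rate control, and reports robust
    Z'-factor assay quality and replicate reproducibility. Includes a
    synthetic screen generator with known ground truth for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
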