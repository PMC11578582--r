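Package: polequant
Title: Polar Fluorescence Asymmetry Analysis for Rod-Shaped Bacteria
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies ribosome-density asymmetry between the old and new
    poles and daughters of rod-shaped bacteria from time-lapse fluorescence
    microscopy. Implements the image-correction chain (rolling-ball background
    subtraction, hot-pixel removal, Richardson-Lucy deconvolution with a
    peak-based iteration selector), old-pole/new-pole lineage polarity
    tracking, half- and quartile-based spatial partition statistics, a
    variance decomposition separating deterministic asymmetry from stochastic
    noise, randomization inference for jointly normalized pair data, and a
    space-competition model relating displaced ribosome volume to
    elongation-rate loss. Includes a synthetic-data generator with known
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
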