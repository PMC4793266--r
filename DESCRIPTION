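Package: sedcarbon
Title: Blue-Carbon Sediment Core Geochronology and Mooring-Disturbance Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying organic-carbon storage and loss in seagrass
    sediments. Implements lead-210 constant flux : constant sedimentation (CF:CS)
    age-depth modelling with surface-mixing and erosion diagnostics, excess
    lead-210 inventories and atmospheric-flux closure, depth-standardized
    organic-carbon and carbonate stock integration with core-compression
    correction, carbon accumulation rates, mooring-induced stock-loss and
    foregone-sequestration accounting, and Euclidean-buffer scar-area
    quantification on rasterized habitat maps. Includes a synthetic core and
    seascape generator with known ground truth for parameter-recovery
    experiments, and a configurable end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
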