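Package: organmiles
Title: Organ Travel Distance and Transport Emissions Under Acuity-Circle Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how acuity-circle organ-allocation policies changed
    organ travel distance and transport carbon emissions. Builds per-organ
    observation windows equidistant around each policy implementation date,
    resolves donor and recipient ZIP centroids to great-circle distances,
    fits an interrupted time series (segmented regression) to monthly mean
    trip distance, extrapolates the pre-policy trend to estimate
    counterfactual excess miles, and converts excess travel into kg CO2e
    under threshold-based travel-mode scenarios. Includes a synthetic
    registry-like cohort generator so the full pipeline is testable without
    restricted transplant-registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    geosphere,
    lmtest,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
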