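Package: canopyfpar
Title: Per-Tree Canopy Profile Features and fPAR-Based Yield Calibration
    from Orchard Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts per-tree canopy profile features (canopy cover as a
    fractional photosynthetically active radiation estimate, canopy volume
    index, mean and maximum canopy height) from a georeferenced digital
    surface model of an orchard together with a parametric planting-grid
    layout. Provides the terrain pipeline (slope-based tree masking,
    morphological closing, bare-earth extraction with nearest-neighbor
    infill, height normalization), calibration statistics against mobile
    lightbar fPAR measurements (zero-intercept slopes tested against the
    1:1 line, predictive R-squared via leave-one-out PRESS, RMSE to the
    identity and regression lines), potential-yield and adjusted-ratio
    models, and a synthetic-orchard scene generator with closed-form
    per-tree truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
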