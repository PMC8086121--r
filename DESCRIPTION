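Package: cycleexposure
Title: Mobile-Sensing Exposure Analysis for Urban Cyclists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse personal exposure of urban
    cyclists to road-traffic noise and nitrogen dioxide from mobile
    sensing campaigns.  Provides a synthetic-data generator (typed road
    networks, 1 Hz GPS traces, per-minute sensor streams with
    moving-average correlated Student-t errors), one-minute trip
    segmentation with energy-based decibel aggregation and inhaled-dose
    computation, descriptive exposure statistics (dB-aware mean/SD,
    within-trip autocorrelation, distance-band Moran's I), generalized
    additive mixed models with moving-average residual structure
    (GAMMAR) fitted by iterated whitened penalized least squares, and
    WHO-guideline-based noise-dose and pollutant-intake hazard curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
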