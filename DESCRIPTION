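Package: geoexpose
Title: Geostatistical Multimedia Exposure Mapping for Censored Environmental Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for national-scale exposure-inequality analysis of
    a persistent contaminant (benzo[a]pyrene as the indicator PAH) measured in
    drinking water, topsoil and ambient air. Left-censored water panels are
    completed by bootstrap-EM multiple imputation, aggregated over the
    distribution network with segments-of-influence temporal weights, and
    rasterized to a 3 x 3 km reference grid. Soil and air concentrations are
    mapped by indicator kriging, source- and emission-proxy construction, and
    regression/residual kriging with linear or random-forest trends. A
    multimedia exposure model converts the media maps into per-pathway Lifetime
    Average Daily Doses and Excess Individual Risk for two age classes, with
    uncertainty and validity overlays. A synthetic scenario generator
    reproduces the statistical structure of the closed monitoring databases so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    yaml,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
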