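Package: STCoverage
Title: Spatio-Temporal Variogram Modelling and Coverage Mapping for
    Air-Quality Monitoring Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the spatial and temporal representativeness of a
    fixed air-quality monitoring network. Hourly concentration records are
    aggregated to a weekly panel under day/hour completeness rules, the
    empirical spatio-temporal semivariogram is estimated from station pairs,
    five space-time covariance structures (separable, product-sum, metric,
    sum-metric and simple sum-metric) built from exponential, spherical and
    Gaussian components are fitted by weighted least squares over the full
    structure-by-family candidate grid, and the fitted spatial correlation
    range is turned into per-year coverage maps as unions of circles around
    the active stations. A seeded Gaussian random-field simulator with
    structured missingness makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
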