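Package: leriscape
Title: Grid-Based Landscape Ecological Risk Assessment with Dynamic Vulnerability
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for landscape ecological risk assessment on a square
    (fishnet) grid of assessment units. Computes per-cell, per-class patch
    metrics (fragmentation, separation, dominance) and a landscape
    disturbance index; a dynamic landscape vulnerability index that
    modulates empirical class ranks by an entropy-weighted composite of
    standardized environmental indicators; and combines them into a
    Landscape Ecological Risk Index (LERI) per cell. Includes temporal
    change statistics (annualized risk rate of change, coefficient of
    variation), five-level risk classification by fixed breaks or Jenks
    natural breaks, land-use transfer matrices, identification of key
    risk-management areas by quantile thresholds, and a neutral-landscape
    synthetic data generator (modified random clusters) for testing and
    demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
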