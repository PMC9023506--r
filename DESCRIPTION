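Package: larvascreen
Title: Behavioral Profiling and Cluster Discovery for Zebrafish Larval
    Drug Screens in Multiwell Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for high-throughput behavioral drug screening
    with zebrafish larvae imaged in 384-well format. Encodes the 3-h,
    18-period visual/acoustic stimulus schedule, simulates per-well larval
    movement and location time series from parametric phenotypes with known
    ground truth (optionally rendering plate-image sequences), re-implements
    frame-differencing image analysis of plate videos, computes the ten
    behavioral outcome measures (baseline activity, habituation, startle,
    excitability, and optomotor responses) with automatic low-movement
    exclusions, screens treatment groups against vehicle controls with
    Welch's test under tiered Bonferroni correction, and discovers
    functionally similar compounds by complete-linkage hierarchical
    clustering of behavioral profiles with down-weighted optomotor features,
    additive-inverse hypothetical profiles, and Cluster-3.0-compatible
    CDT/GTR export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    grDevices,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
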