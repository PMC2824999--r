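Package: cobrachy
Title: Monte Carlo Dosimetry of an Encapsulated HDR Cobalt-60 Brachytherapy
    Source
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Photon-transport Monte Carlo simulation and TG-43 dosimetric
    analysis for the new-design encapsulated BEBIG Co-60 high-dose-rate
    brachytherapy source.  Models the cobalt core, steel capsule and cable
    inside water, PMMA, polystyrene, Solid Water, RW1, air or vacuum
    phantoms; scores collision kerma in cylindrical ring cells with
    track-length estimators and air kerma with next-event point detectors;
    and derives air-kerma strength, the dose-rate constant, the radial dose
    function with its cubic fit, Cartesian dose-rate tables and
    water-equivalence comparisons between phantom materials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
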