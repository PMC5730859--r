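Package: zygoloop
Title: Cohesin Loop Extrusion and Single-Nucleus Hi-C Feature Analysis for Zygotic Chromatin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates cohesin-mediated loop extrusion on a one-dimensional
    chromatin lattice coupled to a coarse-grained three-dimensional polymer,
    and quantifies the structural features of sparse single-nucleus Hi-C
    (snHi-C) contact maps: contact probability scaling P(s) with smoothed
    log-log slopes, aggregate loop and TAD enrichment, compartment saddle
    statistics, insulation profiles, trans-contact fractions, and in-silico
    sorting of maternal and paternal pronuclei. Includes the P(s)-derivative
    method for inferring the average extruded loop size and a cohesin
    linear-density signature from a contact-probability curve, bootstrap and
    permutation statistics for sparse contact maps, and a synthetic
    single-nucleus contact generator with planted loops, TADs, compartments
    and a maternal long-range plateau so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    patchwork
Config/testthat/edition: 3
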