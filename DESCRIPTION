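Package: xomapr
Title: Crossover Mapping and Recombination Landscapes from Fluorescent
    Seed Typing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring and mapping meiotic crossovers in
    plant intervals flanked by seed-expressed fluorescent reporters.
    Estimates genetic map distance (centimorgans) from green-only and
    red-only seed segregation counts with bootstrap confidence
    intervals, calls crossover breakpoint intervals in sequenced
    recombinants from per-marker allele depths via haplotype-block
    segmentation, and aggregates calls into normalized crossover
    distributions, sliding-window cM/Mb tracks, differential
    landscapes, and hotspot-usage statistics. A synthetic-data
    generator with known ground truth makes every stage verifiable by
    parameter recovery, and a pipeline runner ties the stages together
    with deterministic, seeded re-runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    dplyr,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
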