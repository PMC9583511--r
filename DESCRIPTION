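Package: repstress
Title: Single-Cell Copy-Number Landscapes of Replication Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing replication-stress-induced copy-number
    alterations (CNAs) in low-pass single-cell whole-genome sequencing.
    Implements hidden-Markov-model copy-number calling from GC-corrected
    binned read counts, removal of clonal and sub-clonal CNAs with
    high-resolution breakpoint refinement, CNA size/direction
    classification with per-cell rate statistics, single-cell replication
    timing (per-S-phase-fraction binarization and the replication timing
    factor), and association of CNA breakpoints with genomic features
    (large and giant genes, fragile sites, secondary-structure repeat
    density) using Kruskal-Wallis/Dunn and chi-square goodness-of-fit
    statistics against randomly placed in-silico controls. A seeded
    synthetic-data generator emulates G1 and S-phase-fraction single-cell
    read-count profiles with retrievable ground truth so that every stage
    of the pipeline can be validated end-to-end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
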