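Package: sievepool
Title: Size-Fraction Pooling and Downstream Analysis for Bulk-Sample Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of DNA metabarcoding OTU tables from
    size-sorted arthropod bulk samples (for example Malaise trap catches).
    Implements negative-control subtraction, per-sample relative-abundance
    thresholding and extraction-replicate consistency filtering; in silico
    pooling of size-fraction libraries under named lysate-pooling strategies
    including dry-weight-proportional reconstruction of unsorted samples and
    a two-fraction mixing-ratio sweep; threshold-based rarefaction with
    depth-equivalence factors between pooling strategies; OTU size-class
    assignment with richness, fraction-sharing and dissimilarity summaries;
    and a forward simulator of size-structured bulk communities (lognormal
    rank abundance, allometric length-weight scaling, sieving with fragment
    carryover, biomass-proportional multinomial read generation with
    per-species primer bias) that produces OTU tables with known ground
    truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
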