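Package: stemloop
Title: Discovery and Analysis of Plant miRNA Hairpin Precursors from
    Small-RNA Sequencing Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for plant microRNA discovery from collapsed
    small-RNA sequencing tags: exact mapping of 19-24 nt tags to a genome,
    extraction of genomic flanks, Smith-Waterman location of the miRNA-star
    arm from the reverse-complemented tag, validation of stem-loop
    precursors by weighted base-pair-maximisation folding and duplex
    criteria (opposite arms, at most four mismatches, restricted asymmetric
    bulges), classification of accepted miRNAs into novelty classes against
    miRBase-style catalogs, isomiR grouping with +n/CORE/+m pattern
    notation, complementarity-based target scoring with G:U wobble weights,
    and stem-loop RT-qPCR relative expression by the 2^-ddCt method with
    Welch t-tests. Includes a synthetic-data generator that plants
    criteria-compliant hairpins in toy genomes with known truth, and
    packaged reference tables from a soybean stress small-RNA study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
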