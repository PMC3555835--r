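Package: isomiRpipe
Title: IsomiR-Aware Small RNA Profiling, Novel miRNA Discovery and
    Breed-Group Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for multiplexed small-RNA sequencing
    libraries of the 454 era: demultiplexing by 5-nt multiplex identifiers,
    adapter trimming, collapsing to unique tags, end-tolerant annotation
    against a mature microRNA reference with isomiR cluster construction,
    novel miRNA candidate discovery through unique perfect genome mapping
    and hairpin-structure validation, counts-per-thousand normalization
    with signed fold-change differential-expression calls between breed
    groups, RT-qPCR standard-curve calibration with geNorm reference
    stability, and hypergeometric functional enrichment. Includes a
    synthetic-data generator that emulates multi-library kidney small-RNA
    runs with known isomiR structure and planted group expression effects,
    so every stage is testable against simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
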