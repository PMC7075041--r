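Package: strcaller
Title: Targeted Short Tandem Repeat Profiling from Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end targeted profiling of forensic short tandem repeat
    (STR) markers from massively parallel sequencing reads. Parses forensic
    STR sequence-structure nomenclature, calls per-read alleles by exact
    motif tiling anchored between flanking sequences, translates sequence
    alleles into capillary-electrophoresis-compatible repeat designations
    (counting insertions and deletions that fall inside the repeat region),
    derives locus genotypes with noise and stutter-ratio filtering, exports
    a per-locus quality-control feature matrix, and ships a stutter-aware
    amplicon read simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
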