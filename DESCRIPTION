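Package: satay
Title: Saturated Transposon Analysis in Yeast (SATAY) Insertion Maps and Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Turns aligned transposon-junction reads from saturated
    transposon mutagenesis screens in yeast into genome-wide insertion
    maps, and computes the downstream statistics used in such screens:
    per-gene transposon and read counts, essential-gene and
    essential-protein-domain detection via a longest-transposon-free-
    interval likelihood score, multi-library genetic-interaction volcano
    statistics, drug-resistance positive-selection comparisons, and
    genome-scale signal analyses (nucleosome-phase periodicity of the
    insertion density, pericentromeric enrichment). A synthetic-library
    simulator with truth tables makes every stage testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    withr,
    pracma,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
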