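Package: strandrepair
Title: Strand-Specific Analysis of UV Damage Repair from CPD-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing genome-wide repair of UV-induced
    cyclobutane pyrimidine dimers (CPDs) from CPD-seq experiments in a
    strand-specific manner. Converts aligned read 5'-end records into
    dipyrimidine-filtered lesion count tracks, computes the fraction of
    CPDs remaining in metagene bins along the transcribed and
    non-transcribed strands of genes, quantifies transcription-coupled
    repair asymmetry as a log2 TS/NTS ratio, builds single-nucleotide
    TSS-aligned repair profiles with nucleosome dyad overlays, and
    stratifies repair by antisense-transcript gene classes. Includes
    alkaline-gel quantitation of bulk CPD frequencies (number-average
    fragment length, CPDs per kb, percent repair) used to rescale
    sequencing-based repair fractions, UV-survival statistics, and a
    parametric simulator of lesion induction and genotype-dependent
    repair kinetics that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    yaml,
    withr,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
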