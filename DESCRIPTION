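Package: crackle
Title: Crosslink-Site Mapping and Metagene Analysis for CRAC/CLIP Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for UV crosslinking and analysis
    of cDNA (CRAC) sequencing libraries, built around the micro-deletion
    signature that reverse transcription leaves at protein-RNA contact
    sites. Covers in-line barcode demultiplexing with embedded random
    nucleotides (UMIs), adapter trimming and quality filtering, PCR
    duplicate collapsing, seeded short-read alignment with single-deletion
    tolerance, per-nucleotide read/substitution/deletion pileups, crosslink
    site calling and cross-strain comparison, reference-point and
    scaled-region metagene profiling, non-templated oligo(A) tail
    detection, CRAC versus RiboSeq/RNASeq abundance comparison, and
    polysome gradient A260 trace quantification. Includes a synthetic-data
    generator that plants ground-truth crosslink sites, oligo(A) tails and
    PCR duplicate structure so every pipeline stage can be verified against
    a truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
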