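Package: dramseq
Title: Calling m5C-Directed Deaminase Editing Sites from RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of RNA editing events induced by
    m5C-reader/deaminase fusion proteins (DRAM-seq). Provides a synthetic-read
    generator that plants 5-methylcytosine sites on simulated transcripts and
    emits condition-specific alignments, a strand-aware pileup and candidate
    extractor for C-to-U and A-to-G conversions, the multi-tier comparative
    filter cascade against knockout and deaminase-only controls, metagene and
    distance-to-reference profiling, sequence-context position frequency
    matrices, and site-level quantification from bisulfite amplicons and
    Sanger-trace base proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
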