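Package: polysomiR
Title: Polysome-Fraction Small RNA Sequencing Analysis for Drosophila Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for small RNA deep-sequencing of
    polysome-fractionated Drosophila melanogaster embryos around the
    maternal-to-zygotic transition. Implements barcode demultiplexing, a
    four-step 3' adapter trimming cascade, collapsing of 15-29 nt inserts,
    hierarchical annotation against an ordered set of ncRNA reference
    categories with mismatch tiers, mature miRNA quantification (RPM) with
    pseudocount fold changes and a four-group polysome-association
    classifier, and transposon-derived siRNA/piRNA analyses: size-class
    partitioning, the ping-pong 5'-5' overlap spectrum, positional base
    biases (1U/10A) and piRNA-cluster strand profiles. A synthetic-data
    module generates reference collections and multiplexed libraries with
    full ground-truth provenance so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
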