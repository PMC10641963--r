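Package: tescreen
Title: Screening and Structural Curation of Transposable Elements
    Misannotated as Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects transposable elements (TEs) misannotated as
    protein-coding genes by intersecting repeat annotations with CDS
    regions under a full-containment rule, and automates the structural
    curation of candidate hAT DNA transposons: target-site duplication
    (TSD) and terminal-inverted-repeat (TIR) detection, six-frame open
    reading frame finding, alignment-anchored DDE/RW catalytic-residue
    scanning, and an autonomous versus partial classification.  Includes
    a translated-homology screen of gene models against a transposase
    protein library, and a synthetic-genome generator with ground-truth
    tables so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    optparse,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
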