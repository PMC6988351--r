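Package: gobymine
Title: Homology-Based Gene-Family Mining and Screening Toolkit for Fish Genomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of the bespoke comparative-genomics
    procedures used in gene-family studies of teleost genomes: chaining of
    translated-homology (tblastn) hits into multi-exon gene models with
    longest-ORF translation and length filtering; PROSITE-style motif
    scanning and cytochrome P450 completeness classification; NLR-C group
    assignment from Walker A motifs and PYD/B30.2 domain architecture;
    PYD-CARD (ASC) adaptor detection; lineage-specific gene-family
    expansion calling on species-labelled phylogenies; additive
    spectral-tuning (lambda-max) prediction for LWS opsins from key sites
    in bovine-rhodopsin numbering; and a RAD-seq presence/absence screen
    for sex-determining regions. Ships seeded simulators that implant
    gene families, expansions and sex-linked loci with machine-readable
    truth so every analysis step is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    BiocGenerics,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
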