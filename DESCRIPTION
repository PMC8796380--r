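Package: sgedesign
Title: Oligonucleotide Variant Library Design for Saturation Genome Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs and annotates oligonucleotide variant libraries for
    saturation genome editing (SGE), cDNA deep mutational scanning and
    saturation prime editing. Given genomic coordinates ("targetons"),
    transcript annotation and a codon usage table, the package partitions
    each targeton into constant and mutable regions, applies systematic
    nucleotide- and codon-level mutator functions (SNV, single and tandem
    deletions, synonymous/redundant codon expansion, in-frame codon
    deletion, alanine and stop scans, amino-acid scans), incorporates
    custom variants from VCF files and PAM/protospacer protection edits,
    and writes annotated metadata, unique-sequence and VCF outputs ready
    for oligo pool synthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
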