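Package: trimkit
Title: Annotation, Dating, and Population Analysis of TRIM Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for terminal-repeat retrotransposons in miniature (TRIMs):
    structural annotation of intact, solo-LTR, truncated, and multi-LTR tandem
    copies from a consensus model; insertion dating from LTR divergence under
    the Kimura two-parameter model (T = K/2r); split-read detection and
    flanking-sequence genotyping of insertion polymorphisms from paired-end
    short reads; and neighbor-joining phylogeny from the resulting
    presence/absence matrix. Includes a synthetic-data generator that plants
    elements of known age, category, and target-site duplication into random
    genomes, builds group-structured accession panels, and simulates
    paired-end reads with a full ground-truth ledger, so every stage of the
    pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Annotation, Genetics, Phylogenetics, Sequencing, Software
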