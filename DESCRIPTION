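Package: tecur
Title: Curation, Classification and Comparative Annotation of Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for manual-curation-style annotation of
    transposable elements in assembled genomes, centred on endogenous
    retrovirus (ERV)-like LTR retrotransposons and CR1 LINEs of birds.
    Provides a synthetic-genome simulator with full ground truth (ERV
    insertions with target site duplications and solo-LTR formation,
    3'-anchored truncated CR1 copies, transition/transversion-biased
    neutral divergence with CpG hypermutation and optional APOBEC-style
    G-to-A editing), a seed-and-extend nucleotide homology search and
    library masking engine, automated consensus curation (majority-rule
    consensus with CpG restoration, element boundary detection, target
    site duplication and LTR terminal motif checks, 5' extension of CR1
    consensuses), superfamily/family/subfamily classification by TSD
    length and the 80-80-80 and 95% identity rules, cross-genome
    presence/absence with Dollo branch assignment on a species tree,
    Kimura 2-parameter repeat landscapes with CpG down-weighting, masking
    overlap statistics, and ERV copy-structure tools (pseudo full-length
    consensus, coverage profiles, solo-LTR classification, ORF finding).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    XVector,
    GenomicRanges,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
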