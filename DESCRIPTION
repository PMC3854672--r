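Package: tralign
Title: Template-Based RNA Sequence Alignment with Phylogenetic Profiles
    and Secondary-Structure Descriptors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns new RNA sequences into an existing curated template
    multiple sequence alignment. Two complementary engines are provided:
    a phylogeny-stratified column-profile aligner that scores blocks of
    highly conserved columns against per-taxon conservation and
    nucleotide-composition statistics, and a secondary-structure
    descriptor engine that derives ordered structural-element constraints
    (helices and single strands with length, mispair and composition
    histograms) from a reference structure, identifies those elements in
    unaligned sequences by stringency-ranked seeding and bidirectional
    extension, and aligns sequences element by element. Also included are
    pairwise identity and stack-based alignment-accuracy metrics,
    deterministic synthetic template generators for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
biocViews: Alignment, MultipleSequenceAlignment, RNA, Phylogenetics,
    Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
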