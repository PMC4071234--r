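Package: phylomask
Title: Convergence-Aware Parsimony Phylogenetics for GC-Biased Codon Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building gene-family phylogenies from codon alignments in
    the presence of lineage-specific GC mutational bias. Provides codon-aware
    alignment transformations that strip the biased signal (third-codon-position
    removal, G/C-to-N masking, serine-codon first/second-position extraction,
    gap and ambiguity recoding, gappy-block trimming), per-codon-position
    nucleotide composition diagnostics, a maximum-parsimony engine whose
    ambiguity semantics distinguish N (any nucleotide) from ? (any nucleotide or
    gap) with the gap optionally scored as a fifth state, parsimony ancestral
    reconstruction of an unordered five-state protein-morphology character with
    exact counting and enumeration of all most-parsimonious reconstructions, a
    transmembrane-domain-based classifier of PIN protein morphology, and a
    sequence simulator with lineage-specific third-position GC bias that makes
    the whole workflow testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
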