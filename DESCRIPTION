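Package: linmotif
Title: Robust Unsupervised Deconvolution of Linear Sequence Motifs at
    Modified Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects position-specific linear amino-acid motifs in fixed-width
    peptide windows centered on post-translationally modified sites. Candidate
    position/residue pairs (optionally compound physicochemical residue groups)
    are tested for enrichment against a proteome-derived background with an
    exact one-sided binomial test and Bonferroni correction; all equally,
    maximally enriched pairs are fixed simultaneously and the foreground is
    partitioned into possibly overlapping subsets, with the background
    recompiled for each subset, so that motif detection is invariant to input
    order, to the addition of single sequences and to sequence reversal.
    Includes window extraction from FASTA proteomes with site tables,
    multi-sample pattern match matrices, positional load and composition
    summaries, clustering-ready matrix transforms, synthetic data generators
    for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
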