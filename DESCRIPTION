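Package: pamlsubs
Title: Substitution Patterns from PAML Ancestral Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of ancestral sequence reconstructions produced
    by PAML's baseml and codeml programs. Parses the auxiliary 'rst' output
    file into a structured document, classifies every inferred substitution
    by transition/transversion type, codon position and phenotypic effect
    (synonymous vs nonsynonymous), computes per-site profiles,
    sliding-window dN/dS series and cumulative substitution curves, builds
    a Markov matrix of conditional substitution probabilities, annotates
    phylogenetic trees with per-branch substitution summaries, and exports
    plots, tabular reports and annotated Newick trees. Includes a seeded
    codon-evolution simulator that writes synthetic rst files together with
    an exact event log, so every stage of the pipeline can be validated
    against a known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
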