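Package: channelome
Title: Ion-Channel Annotation Modelling, Orthology Inference, and
    Phylogenetic Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating and analysing the complement of ion-channel
    (IC) proteins in a proteome. Models a curated IC annotation table with
    membrane-segment parsing, pore-domain derivation and pore-containing
    versus auxiliary classification; infers orthologs across proteomes by
    dual-evidence (full-length and pore-domain) reciprocal best hits with
    Markov graph clustering and a three-step metadata validation cascade;
    builds phylogenetic presence/absence profiles with Ward clustering and
    hypergeometric term enrichment; and detects subfamily-diagnostic
    conserved pattern positions in multiple sequence alignments with a
    contrast statistic and permutation significance. A synthetic-data
    generator with recorded ground truth (gene duplication and loss on a
    taxonomy, slowly evolving pore subregions, planted metadata defects,
    planted alignment patterns and planted term enrichment) makes every
    stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
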