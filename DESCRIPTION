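Package: cdpsminer
Title: Genome Mining of Cyclodipeptide Synthases and Their Products
Version: 0.1.0
Authors@R: person("cdpsminer", "developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects cyclodipeptide synthases (CDPSs) in prokaryotic genomes
    with profile hidden Markov models, classifies them into the NYH, XYP and
    SYQ subfamilies, extracts the P1 and P2 substrate-binding pocket residues
    by alignment to a reference CDPS (AlbC-anchored), predicts the two
    aminoacyl-tRNA substrates with a naive Bayes classifier, assembles the
    surrounding biosynthetic gene cluster (within 2.5 kb) with tailoring and
    resistance domain annotation, generates predicted diketopiperazine
    structures including combinatorial tailoring libraries scored by circular
    fingerprint Tanimoto similarity, and maps unique CDPSs into sequence
    similarity networks. Ships a deterministic synthetic-data generator so the
    entire pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
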