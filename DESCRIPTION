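Package: tolton
Title: Genome Mining and Structural Composition Analysis of Tol-Pal and
    Ton Force-Transduction Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tol-pal and Ton force-transduction loci in
    domain-annotated bacterial genomes, disambiguates the TolA and TonB
    force transducers by genomic context, segments transducers into their
    three-domain architecture from secondary-structure profiles,
    quantifies domain II alpha-helix and proline composition and
    motor-box presence, and aggregates per-protein records into cohort
    statistics (length summaries, correlation, rank tests, adjacency and
    lipidation proportions). Ships a synthetic-data generator that plants
    complete, split, partial and Ton-only systems in annotated genomes so
    every pipeline stage is testable without external databases or
    structure predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    rtracklayer,
    Biostrings
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
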