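Package: pdvnet
Title: Protein-Damage Variant Scoring, Cross-Trait Interaction Networks, and
    Biological-Process Dysfunction Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for rare-variant pathway burden in
    neurodevelopmental cohorts. Aggregates in-silico deleteriousness
    predictions into per-variant predicted-damaging (PDV) scores with
    pseudoautosomal-aware zygosity weighting and CNV handling, restricts two
    candidate gene sets (e.g., autism and sleep-duration genes) to
    PDV-bearing genes, extracts the cross-trait protein-protein interaction
    subnetwork, detects overrepresented Gene Ontology biological processes
    with a topology-aware elimination procedure, computes per-individual
    evidence-weighted dysfunctional-biological-process (DBP) scores,
    validates against feature-matched random gene sets, and tests DBP scores
    for association with sleep duration. Includes a synthetic-cohort
    generator with planted ground truth so every stage is testable without
    access-restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
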