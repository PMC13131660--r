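Package: cretrace
Title: Retracing and Rewriting the Functional Evolution of Enhancers
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the functional evolution of cis-regulatory
    elements (CREs) across a phylogeny and for rewriting their activity with
    model-guided mutational trajectories. Covers pairwise global alignment of
    orthologs with deterministic mutation-event enumeration, PSAM-based
    transcription factor binding site (TFBS) affinity scanning with
    random-k-mer normalization, lineage step-change analysis over labeled
    phylogenies, greedy oracle-guided reconstitution of extant enhancers from
    ancestral sequences, de novo enhancement and ablation tuning, MPRA
    (massively parallel reporter assay) barcode quantification with winsorized
    RNA/DNA activity estimates, additive and multiplicative epistasis
    analytics, and a synthetic-data simulator that evolves sequences along a
    tree with planted motif gain and loss events.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
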