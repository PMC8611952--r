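Package: chemogenlib
Title: Chemogenomics Library Design from Bioactivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of diversity-optimised chemogenomics compound
    libraries from ChEMBL-style bioactivity tables. Implements scaffold-tree
    decomposition of molecules (Murcko framework, stepwise one-ring removal),
    high-confidence bioactivity filtering, promiscuous-scaffold pruning,
    Jaccard hierarchical clustering of scaffold bioactivity profiles with a
    deterministic representative-selection cascade, elitist non-dominated
    (Pareto) genetic-algorithm subset selection under three coverage
    objectives, target-coverage completion, per-compound hypergeometric
    term enrichment (GO/KEGG/Disease Ontology) with Bonferroni adjustment,
    Cell Painting morphological-feature processing, and export of the full
    pharmacology network as a property graph (GraphML or Neo4j bulk-import
    CSV). Includes seeded synthetic-data generators emulating every input so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
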