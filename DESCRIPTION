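Package: tfnetminer
Title: Literature-Mined Transcription-Factor Interaction Networks and
    Multi-Parametric Node Prioritization
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds disease-specific transcription-factor (TF) interaction
    networks from a corpus of abstracts and ranks TFs and TF-anchored
    modules by combined topological and biological evidence.  Gene pairs
    are scored by tf*idf co-occurrence association, validated by
    Czekanowski-Dice Gene Ontology annotation distance and by a
    structure-based interaction algorithm on C-alpha contacts, assembled
    into an undirected network annotated with degree, clustering
    coefficient and betweenness, prioritized by un-weighted and weighted
    node strength and hypergeometric node-node association, decomposed
    into TF ego-network modules, and finally interpreted by hypergeometric
    pathway enrichment against user-supplied gene sets.  Deterministic
    synthetic-fixture generators (corpora, thesauri, GO annotations, toy
    structures, pathway collections) make every stage testable end-to-end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    bio3d,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
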