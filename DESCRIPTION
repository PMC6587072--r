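Package: belcurate
Title: Rational Enrichment and Re-Curation of Biological Expression Language Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the semi-automated maintenance of causal biological
    knowledge graphs encoded in a subset of the Biological Expression
    Language (BEL). The package parses and writes BEL Script documents,
    collapses gene-centric graphs and ranks genes by information density
    (in-degree plus out-degree) to prioritise curation, triages
    machine-extracted relation corpora by novelty and belief score,
    assembles extracted statements into candidate BEL edges, generates and
    re-ingests tab-separated curation sheets under a six-rule marking
    protocol, scores curation quality (accuracy, recovery, error-type
    profiles, throughput), and implements a multi-curator Likert confidence
    workflow for re-curation quality assurance. A synthetic-fixture module
    generates knowledge graphs, statement corpora with planted error
    structure and simulated curator decisions so that the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
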