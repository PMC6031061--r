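Package: ontoscout
Title: Ontology-Guided Search and Exploration of Annotated Dataset Repositories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns bio-ontologies (OBO / OWL RDF-XML) plus a manifest of
    ontology-annotated datasets into a pruned strict-containment exploration
    graph with per-term statistics. Computes the transitive annotation closure,
    hides unused terms, collapses redundant equal-set ancestors, evaluates
    combined free-text and Boolean annotation-term queries with synonym
    expansion and keyword-in-context snippets, derives per-term precision and
    recall for any result set, and emits renderer-agnostic treemap and layered
    node-link layout geometry. Includes a deterministic synthetic-fixture
    generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
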