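Package: skosmerge
Title: Provenance-Tracked Integration of Multiple Disease Classifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates two or more expert classifications of a disease domain
    (nosology-style groupings, disorder sub-typing, gene and phenotype
    associations with optional frequency qualifiers) into a single knowledge
    graph with statement-level provenance. Grouping uses SKOS Collection
    semantics, sub-typing uses the mutually inverse transitive broader/narrower
    relations, and every entity and statement carries a PROV-style attribution
    to the agents that asserted it. Supports expert alignment tables, a
    deterministic RDF Turtle serialization with OWL 2 annotated axioms and
    punning, per-source provenance views for recreating any contributing
    classification, comparative coverage and association analytics, and
    reproducible synthetic two-source fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
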