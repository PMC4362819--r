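Package: itoenrich
Title: Interaction-Type Ontology Enrichment for Literature-Mined Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ontology-driven analysis of literature-mined gene-gene
    interaction networks. Parses an interaction-type ontology (a rooted is_a
    DAG whose terms carry literature-mining keyword annotations), tags gene
    pairs and interaction keywords in sentence corpora by dictionary matching,
    propagates pair annotations up the ontology hierarchy, and identifies
    interaction types significantly over- or under-represented in a
    concept-specific sub-network relative to the whole network using a
    conservative "minus one" modified Fisher's exact test with
    Benjamini-Hochberg correction. Includes a seeded synthetic-data generator
    (toy ontologies, lexicons, template corpora with planted enrichment) and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
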