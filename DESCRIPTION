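Package: rdfquality
Title: Automated Foundational Quality Assessment of RDF Resources
Version: 0.1.0
Authors@R: person("RDF", "Quality Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Computes six foundational, objective, automatable quality
    metrics for RDF resources (linked-data datasets, schemas, and
    ontologies): non-resolvable URIs, non-parsable URIs, undefined URIs,
    misplaced classes or properties, misuse of owl:DatatypeProperty or
    owl:ObjectProperty, and use of deprecated classes or properties.
    Resources in Turtle, RDF/XML, N-Triples, Notation 3, or JSON-LD are
    parsed, every unique URI is dereferenced with content negotiation,
    defined terms are classified as classes or properties and checked for
    deprecation, and the results are written as CSV reports and as RDF
    quality metadata aligned with the Data Quality Vocabulary (DQV).
    Includes a deterministic synthetic linked-data ecosystem generator
    with injected defects and a local fixture HTTP server so that every
    metric is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    curl,
    httpuv,
    callr,
    utils,
    tools,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
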