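Package: sparqlexamples
Title: Curate, Validate, Analyze and Publish SPARQL Query Example Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for maintaining collections of natural-language-question plus
    SPARQL-query examples over (federated) bioinformatics knowledge graphs. Examples
    are stored one per Turtle file using the SHACL SPARQLExecutable vocabulary with
    Schema.org annotations. The package reads and writes this representation,
    validates metadata and query syntax, computes per-query complexity metrics
    (triple patterns, aggregations, federation), renders query graphs as Mermaid
    diagrams with property-path decomposition, rewrites vendor SPARQL extensions
    (named subqueries, missing prefixes, engine hint triples) into standard SPARQL 1.1,
    merges examples into per-endpoint named graphs, generates VoID dataset
    descriptions that drive schema-aware query autocomplete, and checks endpoint
    metadata compliance. Includes a deterministic synthetic fixture generator and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
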