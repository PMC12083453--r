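# SHACL shapes documenting the metadata contract enforced by the validator
# (mandatory fields, language-tagged question, one query property). The R
# validator implements these rules natively; this file is the declarative
# statement of the same contract for SHACL-capable consumers.

@prefix sh: <http://www.w3.org/ns/shacl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix schema: <https://schema.org/> .
@prefix spex: <https://purl.expasy.org/sparql-examples/ontology#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix ex: <https://example.org/shapes/> .

ex:ExampleShape
    a sh:NodeShape ;
    sh:targetClass sh:SPARQLExecutable ;
    sh:nodeKind sh:IRI ;
    sh:property [
        sh:path rdfs:comment ;
        sh:minCount 1 ;
        sh:severity sh:Violation ;
        sh:message "an example needs at least one question (rdfs:comment)" ;
    ] ;
    sh:property [
        sh:path schema:target ;
        sh:minCount 1 ;
        sh:nodeKind sh:IRI ;
        sh:severity sh:Violation ;
        sh:message "an example needs at least one target endpoint (schema:target)" ;
    ] ;
    sh:property [
        sh:path rdfs:comment ;
        sh:qualifiedValueShape [ sh:datatype <http://www.w3.org/1999/02/22-rdf-syntax-ns#langString> ] ;
        sh:qualifiedMinCount 1 ;
        sh:severity sh:Violation ;
        sh:message "at least one question must carry a language tag" ;
    ] .

ex:SelectShape
    a sh:NodeShape ;
    sh:targetClass sh:SPARQLSelectExecutable ;
    sh:property [
        sh:path sh:select ;
        sh:minCount 1 ; sh:maxCount 1 ;
        sh:severity sh:Violation ;
        sh:message "a SELECT example carries exactly one sh:select query" ;
    ] .

ex:AskShape
    a sh:NodeShape ;
    sh:targetClass sh:SPARQLAskExecutable ;
    sh:property [
        sh:path sh:ask ;
        sh:minCount 1 ; sh:maxCount 1 ;
        sh:severity sh:Violation ;
        sh:message "an ASK example carries exactly one sh:ask query" ;
    ] .
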