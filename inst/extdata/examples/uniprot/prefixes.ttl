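PREFIX sh: <http://www.w3.org/ns/shacl#>
PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>

_:sparql_examples_prefixes
    sh:declare [ sh:prefix "up" ; sh:namespace "http://purl.uniprot.org/core/"^^xsd:anyURI ] .
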