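# Namespace IRIs used across the package (collated first).

XSD <- "http://www.w3.org/2001/XMLSchema#"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
SH_NS <- "http://www.w3.org/ns/shacl#"
SCHEMA_NS <- "https://schema.org/"
SCHEMA_NS_HTTP <- "http://schema.org/"
SPEX_NS <- "https://purl.expasy.org/sparql-examples/ontology#"
VOID_NS <- "http://rdfs.org/ns/void#"
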