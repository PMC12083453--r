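# sparqlexamples

Bioinformatics knowledge graphs exposed through SPARQL endpoints (UniProt,
Bgee, OMA, and many others) ship collections of representative
natural-language questions paired with the SPARQL queries that answer them.
When those question–query pairs are stored in a standardized, machine-readable
form, the same examples can drive documentation pages, query editors, search
interfaces, endpoint tests, and training data for question-to-query
translation — across every endpoint that adopts the format.

`sparqlexamples` is an R toolchain for maintainers of such collections. It
implements:

- **The representation.** One example per Turtle file, modeled as a SHACL
  `sh:SPARQLExecutable` (with the subtype matching the query form, e.g.
  `sh:SPARQLSelectExecutable`): the question as a language-tagged
  `rdfs:comment`, the query under `sh:select` / `sh:ask` / `sh:construct` /
  `sh:update` / `spex:describe` (DESCRIBE is not representable in SHACL, so a
  dedicated property under `https://purl.expasy.org/sparql-examples/ontology#`
  is used), endpoints as `schema:target`, tags as `schema:keywords`, federation
  declared with `spex:federatesWith`, and shared prefix declarations via
  `sh:prefixes`. Reading, writing, and collection loading
  (`parse_example()`, `serialize_example()`, `load_collection()`).
- **Validation** (`validate_example()`, `validate_collection()`): strict
  SPARQL 1.1 syntax (double-checked by re-parsing a serialization of the
  algebra), mandatory metadata fields, language tags, type/query consistency,
  and the federation rule — an example declared federated must actually
  contain a `SERVICE` clause. Findings use a closed set of issue codes.
- **Execution probes** (`probe_example()`): queries are rewritten so their
  effective result limit is exactly 1 (`rewrite_query_limit()`), then run
  against a local RDF graph — or, only on demand, a remote endpoint.
- **Complexity analytics** (`analyze_query()`, `collection_stats()`):
  triple-pattern counts (sequence property paths of length *k* count as *k*,
  matching the visual decomposition), aggregation counts, federation
  detection, and per-endpoint summary tables.
- **Visualization** (`build_query_graph()`, `render_mermaid()`,
  `render_markdown_page()`): each query becomes a Mermaid graph with numbered
  edges, projected variables highlighted, property paths decomposed through
  anonymous nodes, and SERVICE bodies grouped in a subgraph naming the remote
  endpoint; one Markdown page per example plus an index.
- **SPARQL 1.1 fixing** (`fix_query()`): prepend missing PREFIX declarations
  from a registry, inline Blazegraph/Anzo `WITH {…} AS %name` / `INCLUDE`
  named subqueries as standard subselects, and strip vendor "magic" hint
  triples that would break the query on other engines.
- **Publishing** (`merge_collection()`, `named_graph_iri()`,
  `query_for_queries()`, `export_bioquery_json()`): per-endpoint merged
  Turtle, the `<endpoint>/.well-known/sparql-examples` named-graph
  convention, keyword search over published examples, and the JSON export
  for the Bio-Query template interface.
- **VoID and autocomplete** (`generate_void()`, `suggest_completions()`,
  `check_metadata_compliance()`): dataset descriptions with class/property
  partitions and class–property linkage, schema-aware completion suggestions
  driven by them, and an endpoint metadata compliance checker with concrete
  remediation suggestions.
- **Synthetic fixtures** (`generate_fixture_collection()`,
  `generate_toy_dataset()`): deterministic collections over a closed query
  grammar with optional defect injection, plus a toy dataset on which every
  clean fixture query returns results — so the whole toolchain is testable
  offline.

Because no RDF or SPARQL infrastructure exists in the R ecosystem used here,
the package includes its own Turtle/TriG reader and writer, a strict SPARQL
1.1 parser, and a small in-memory SPARQL engine used for local probes and
merged-graph queries.

## Worked example

```r
library(sparqlexamples)

path <- system.file("extdata", "examples", "uniprot", "001.ttl", package = "sparqlexamples")
doc <- parse_example(paste(readLines(path), collapse = "\n"))
doc
#> <example_document> https://sparql.uniprot.org/.well-known/sparql-examples/001
#>   kind:     select
#>   question: Select all taxa from the UniProt taxonomy (@en)
#>   targets:  https://sparql.uniprot.org/sparql/
#>   keywords: taxa.

validate_example(doc)
#> <validation_report> 1 example(s) checked: PASSED

analyze_query(doc$query)
#> <query_metrics> select query: 1 triple pattern(s), 0 aggregation(s)
```

The one triple pattern (`?taxon a up:Taxon`) is exactly what the diagram
shows — the projected variable is styled, the edge carries its ordinal:

```r
cat(render_mermaid(build_query_graph(doc$query,
  prefixes = prefix_map(up = "http://purl.uniprot.org/core/")))$text)
#> graph TD
#>   v__x3Ftaxon["?taxon"]:::projected
#>   i__x3Chttp_..._x3E["up:Taxon"]
#>   v__x3Ftaxon -- "1. a" --> i__x3Chttp_..._x3E
#>   ...
```

A synthetic collection exercises the collection-level tooling end to end:

```r
spec <- fixture_spec(n_examples = 12, seed = 7)
generate_fixture_collection(spec, "coll")
coll <- load_collection("coll")
collection_stats(coll)
#>                                endpoint n_queries n_federated mean_triple_patterns total_aggregations
#> 1 https://sparql.omabrowser.org/sparql/         4           1                  2.0                  1
#> 2    https://sparql.uniprot.org/sparql/         5           0                  1.4                  3
#> 3          https://www.bgee.org/sparql/         4           0                  2.8                  1

merge_collection(coll, "https://sparql.uniprot.org/sparql/")
#> <merged_graph> 5 example(s) for https://sparql.uniprot.org/sparql/
#>   named graph: https://sparql.uniprot.org/sparql/.well-known/sparql-examples
```

Each row is one target endpoint: how many examples target it, how many of
those are federated, and the average number of triple patterns per query — a
join-count proxy for query complexity.

## Command line

```sh
Rscript inst/cli/sparql-examples.R validate examples/        # exit 0 = valid, 1 = issues
Rscript inst/cli/sparql-examples.R stats examples/ --out stats.tsv
Rscript inst/cli/sparql-examples.R viz examples/ --out pages/
Rscript inst/cli/sparql-examples.R merge examples/ --endpoint https://sparql.uniprot.org/sparql/
Rscript inst/cli/sparql-examples.R void data.ttl --iri https://example.org/dataset
Rscript inst/cli/sparql-examples.R check dump.trig --endpoint https://sparql.uniprot.org/sparql/
```

Exit codes: 0 success/pass, 1 validation or compliance failures, 2 usage or
configuration error. Nothing touches the network unless `--network` is
passed.

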