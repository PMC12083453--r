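---
title: "Curating SPARQL query example collections: representation, validation, analytics"
author: "sparqlexamples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating SPARQL query example collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparqlexamples)
```

## The problem

Life-science knowledge graphs are published behind SPARQL endpoints, and each
endpoint's maintainers accumulate representative question–query pairs to help
users get started. Kept as free text on web pages, these examples are
invisible to machines: they cannot be tested, searched across endpoints,
rendered, or reused as training data. This package implements a toolchain
around a standardized RDF representation of such examples, so that one set of
services — validation, probing, statistics, visualization, repair,
publishing, autocomplete — works uniformly across every collection that
adopts the format.

## The representation

One example lives in one Turtle file inside a folder named after the
resource that contributed it. The example subject is a SHACL
`sh:SPARQLExecutable`, additionally typed with the subtype matching the query
form (`sh:SPARQLSelectExecutable`, `sh:SPARQLAskExecutable`, ...):

* the natural-language question is an `rdfs:comment` literal carrying a
  language tag (multilingual questions are simply several tagged literals);
* the query text hangs off the property that names its form: `sh:select`,
  `sh:ask`, `sh:construct`, `sh:update` — or `spex:describe` for DESCRIBE
  queries, which SHACL itself cannot represent; a DESCRIBE example is
  therefore typed `sh:SPARQLExecutable` only
  (`spex:` = `https://purl.expasy.org/sparql-examples/ontology#`);
* `schema:target` lists every endpoint where the query runs as-is (an
  example may have several targets, and then counts toward each);
* `schema:keywords` carries free-text tags, preserved verbatim
  (normalization is the caller's concern);
* `spex:federatesWith` declares the remote endpoints of a federated query;
* `sh:prefixes` points to a node of `sh:declare` prefix declarations that
  several files may share.

Two conventions in the package fill gaps the representation leaves open.
First, the shared prefix node: when a file references
`_:sparql_examples_prefixes` without defining it, `load_collection()`
resolves the declarations from a `prefixes.ttl` in the same resource folder.
Blank nodes are file-scoped in RDF, so this is a naming convention, not RDF
semantics — which is exactly why it is implemented at the collection loader,
not the parser. Second, a file carrying more than one query property is
rejected as a structure error rather than interpreted as a multi-query
document: one file, one example.

`serialize_example()` writes one predicate–object pair per line. That layout
is a stability contract the defect-injecting fixture generator relies on
(deleting one line leaves valid Turtle), and it makes diffs reviewable.

## Validation

`validate_example()` applies a closed set of rules; every finding is
reported, never thrown:

| rule | code(s) | severity |
|------|---------|----------|
| query parses under the strict SPARQL 1.1 grammar, after expanding the `sh:prefixes` declarations | `SYNTAX_ERROR` | error |
| mandatory fields: IRI identifier, SHACL type, ≥ 1 question, ≥ 1 target | `MISSING_ID`, `MISSING_TYPE`, `MISSING_COMMENT`, `MISSING_TARGET` | error |
| ≥ 1 question carries a language tag | `MISSING_LANGUAGE_TAG` | error |
| declared subtype ↔ query property ↔ parsed query form all agree | `TYPE_QUERY_MISMATCH` | error |
| declared federated (via `spex:federatesWith` or the keyword `federated`) ⇒ the *parsed algebra* contains a SERVICE node | `FEDERATED_WITHOUT_SERVICE` | error |
| SERVICE present but federation not declared | `UNDECLARED_FEDERATION` | warning |
| collection level: duplicate identifiers, unreadable files | `DUPLICATE_ID`, `LOAD_FAILURE` | error |

Design notes:

* **Two parsing passes.** Mature toolchains check syntax with two independent
  parsers; here there is one parser, so the redundancy is approximated by
  serializing the parsed algebra back to SPARQL and re-parsing it. A
  disagreement between the passes is reported as a syntax error.
* **Native rules rather than a SHACL engine.** No SHACL engine exists in this
  R stack, so the metadata rules run as native checks; the equivalent shapes
  ship as `inst/extdata/shapes/example-shapes.ttl` as the declarative
  statement of the same contract.
* **Federation is checked on the algebra**, not the raw text, so the word
  "service" in a string literal cannot produce a false positive.
* **SERVICE without declaration is a warning**, not an error: a query may
  legitimately use SERVICE as an implementation detail the author chose not
  to advertise; the reverse direction (declared but absent) is a hard error
  because it makes the metadata wrong.

### Probes

`probe_example()` checks that a query retrieves at least one result without
putting load on anyone's server: SELECT/CONSTRUCT/DESCRIBE queries are
rewritten so their effective result limit is exactly 1, ASK runs unchanged,
UPDATE is refused outright. The rewrite (`rewrite_query_limit()`) is
textual and position-targeted — only the top-level LIMIT integer changes (or
a LIMIT clause is appended), so comments and formatting survive byte-for-byte
and removing the injected token restores the original query. A pre-existing
`LIMIT 0` is kept and flagged rather than silently "fixed". Probes run
against a local graph by default; remote execution requires an explicit
`network_allowed = TRUE` and is meant for on-demand use by query authors,
never for CI.

When a local probe meets a SERVICE clause, the SERVICE body is evaluated
against the same local graph. This keeps probing fully offline; it means a
local probe of a federated query checks the query's shape, not the remote
endpoint's content.

## Counting triple patterns

The average number of triple patterns per query is the collection's
complexity headline, so the counting convention matters and is stated
explicitly: basic triple patterns are counted in **all** group graph
patterns — OPTIONAL, UNION branches, MINUS, GRAPH, SERVICE bodies,
subqueries, and EXISTS bodies — because each is a join the engine must
perform. A sequence property path `p1/p2/…/pk` counts as *k* patterns,
consistent with the visual decomposition described below; non-decomposable
path operators (alternation, `*`, `+`, `?`, negated sets) count as 1; VALUES
contributes 0 because it joins constants rather than traversing the graph.
Means are kept exact internally and rounded to one decimal only for display.

## Visualization

`build_query_graph()` turns each basic triple pattern into one numbered
edge. Sequence paths are decomposed through fresh anonymous nodes
(`_anon1`, `_anon2`, … in pattern order — a counter, never randomness, so
output is byte-deterministic and golden-file-testable); inverse paths flip
subject and object; other path operators stay one edge labeled with the path
expression. Projected variables carry a dedicated style class, anonymous
nodes render as small circles, OPTIONAL/UNION/MINUS/subquery edges are
dashed with a context tag (nested subgraphs are reserved for SERVICE, where
the subgraph names the remote endpoint — nesting everything makes Mermaid
output illegible). Node ids hex-escape every non-alphanumeric character,
which is total and injective, so distinct terms can never collide. Literal
labels truncate at 30 characters. The edge count always equals the
analyzer's triple-pattern count — both walk the same decomposition.

## Fixing vendor extensions

Three fixes run in a fixed pipeline order (prefixes → named subqueries →
hints), each recorded with a code so the change is auditable:

1. **Missing prefixes** are resolved from a registry of common namespaces
   with a project overlay that shadows on collision. The scan is token-level
   over text with strings, IRIs and comments masked out — deliberately not a
   parse, because a query missing prefixes does not parse.
2. **Named subqueries** use the Blazegraph/Anzo dialect
   (`WITH { SubSelect } AS %name` before WHERE, `INCLUDE %name` in group
   patterns), the dialect the Wikidata community uses. Each INCLUDE is
   replaced in place by the braced subselect; multiple INCLUDEs duplicate it
   (duplication is semantically safe; naming-apart is not expressible in
   standard SPARQL 1.1). A declared-but-never-included block is dropped with
   a warning.
3. **Hint triples** (Blazegraph `http://www.bigdata.com/queryHints#`, AWS
   Neptune `http://aws.amazon.com/neptune/vocab/v01/QueryHints#`, both
   configurable) match no data on other engines and would silently empty the
   result set. Statements whose subject or predicate falls in a hint
   namespace are removed by character-span splicing using the statement
   offsets the parser records, so comments and formatting outside removed
   spans survive verbatim. If removal empties the WHERE pattern the query
   was all hints, and that is an error.

The pipeline guarantees the result parses under the strict grammar and is
idempotent: a second run applies no fixes.

## Publishing and retrieval

Merged per-endpoint Turtle is intended for upload to the named graph
`<endpoint>/.well-known/sparql-examples` (a trailing slash on the endpoint
is joined directly; otherwise a slash is inserted). Once published,
examples are found by querying the endpoint itself; `query_for_queries()`
runs the canonical pattern — `?ex sh:select ?query . ?ex rdfs:comment
?question . FILTER(CONTAINS(?question, keyword))` — with case-sensitive
matching by default (an `ignore_case` flag is offered). The Bio-Query JSON
export assigns each example the category of its contributing resource and
prefers the first English question as its label; the field names are this
package's documented schema.

## VoID and autocomplete

`generate_void()` counts exhaustively: `void:classPartition` entities are
distinct typed subjects, `void:propertyPartition` counts triples per
predicate (these sum to `void:triples` — a conservation invariant the tests
enforce on random graphs), and a linkage table records (subject class,
property, object class, count), where the object class is the object's
`rdf:type` when typed, its literal datatype for literals, and an `unknown`
marker otherwise. Subjects with several types contribute linkage rows for
each; only the per-property conservation is global. Standard VoID has no
linkage vocabulary, so the serialization nests property partitions inside
class partitions with `void:class` pointing at the object class — a
documented convention.

Autocomplete reads only this description: with a known focus class,
suggested predicates are exactly those occurring with that class (soundness:
every suggestion is witnessed by a triple), ranked by descending count with
lexicographic tie-breaks; an unknown focus class falls back to all property
partitions, flagged unscoped. The compliance checker runs the same two
checks a maintainer cares about — a well-formed example graph under the
well-known IRI, and a VoID description with at least one class partition —
and emits a concrete remediation suggestion per failure.

## The synthetic fixture generator

The generator emulates the shape of a real multi-resource collection at desk
scale: by default 20 examples across three resources (bgee, uniprot, oma)
with their endpoint IRIs, a federated fraction of 0.1 (collections of this
kind run at roughly one federated query in ten), English questions with a
French translation on every fifth example, and every seventh example given a
second target endpoint to exercise multi-target semantics. Queries come from
a closed grammar of fifteen templates (0–8 triple patterns; OPTIONAL, UNION,
MINUS, FILTER, aggregates, sequence paths, subqueries, SERVICE), each with
its triple-pattern count recorded by construction — which gives the analytics
tests an expectation independent of the analyzer. Defect injection mutates
otherwise-valid files by line surgery and records (file, code) in a JSON
manifest, so detection tests compare the validator's findings against ground
truth exactly. Determinism is part of the contract: identical spec and seed
give byte-identical trees (R's Mersenne-Twister with fixed sample semantics,
no reliance on container iteration order).

The toy dataset (default 6 taxa, 10 proteins with labels, scientific names
containing the token "species", organism links, and disease annotations) is
arranged so every clean template query returns at least one row. What the
fixtures deliberately do not emulate: the scale and schema heterogeneity of
real knowledge graphs, HTTP content negotiation, endpoint availability, or
statistically realistic query complexity. Green tests therefore demonstrate
the machinery — parsing, rule checking, counting, rewriting, publishing —
not the behavior of any real endpoint.

## Numerical and engineering choices

* **RDF and SPARQL infrastructure is built in.** The R stack here has no RDF
  parser, SPARQL parser, or SPARQL engine, so the package carries its own:
  a Turtle/TriG/N-Triples/N-Quads reader-writer, a strict recursive-descent
  SPARQL 1.1 parser producing an explicit algebra, and a small in-memory
  engine over solution tables (data.frames of encoded terms). The engine
  covers what the toolchain needs — BGPs with property paths, OPTIONAL,
  UNION, MINUS, GRAPH, subselects, aggregates, the common built-ins — and
  refuses what it cannot evaluate rather than guessing; UPDATE is never
  executed. It is cross-checked against an independent engine (Python
  rdflib) on small fixtures in the test suite.
* **Graph isomorphism** (for round-trip tests) matches ground triples as
  multisets and blank nodes by signature refinement plus bounded
  permutation within signature classes — exact for the small graphs examples
  produce, with an explicit error rather than a wrong answer when the blank
  node structure is too ambiguous.
* **FROM clauses are informational in local evaluation**: the supplied graph
  *is* the dataset. This is what makes the canonical taxa query (which names
  a remote graph) probeable against a local fixture.
* **Problem sizes.** The shipped tests and the acceptance script run at desk
  scale: 500 grammar-generated queries for the counting oracle, 20 seeded
  collections of 10 examples for defect detection, 100 random graphs of a
  few dozen triples for VoID conservation. These sizes were chosen to make
  the properties non-vacuous across templates and seeds while keeping the
  whole suite fast to run routinely.

## Known limitations

* The SPARQL parser covers the grammar that example collections use; exotic
  corners (full UPDATE grammar, GROUP BY function-call keys beyond the common
  forms) are parsed loosely or rejected explicitly.
* The local engine is a correctness tool for small graphs, not a query
  optimizer; property-path closure is computed by fixpoint iteration.
* Remote probing uses a minimal SPARQL-protocol GET and is best-effort by
  design; it is opt-in and not exercised offline.
* The compliance checker inspects dumps or local datasets; probing a live
  endpoint is a thin wrapper over the same checks and shares the network
  opt-in.
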