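# Example document model: Turtle parsing, serialization, collection loading.

test_that("the canonical select example parses with all its metadata", {
  doc <- parse_example(taxa_example_ttl())
  expect_equal(doc$kind, "select")
  expect_equal(doc$comments$text, "Select all taxa from the UniProt taxonomy")
  expect_equal(doc$comments$lang, "en")
  expect_equal(doc$targets, "https://sparql.uniprot.org/sparql/")
  expect_equal(doc$keywords, "taxa.")   # preserved verbatim, trailing dot included
  expect_match(doc$query, "?taxon a up:Taxon", fixed = TRUE)
  expect_true(paste0("http://www.w3.org/ns/shacl#", "SPARQLSelectExecutable") %in% doc$declared_types)
})

test_that("describe and ask documents derive their kind from the query property", {
  desc <- parse_example(paste0(
    "@prefix sh: <http://www.w3.org/ns/shacl#> .\n",
    "@prefix spex: <https://purl.expasy.org/sparql-examples/ontology#> .\n",
    "<http://e/1> a sh:SPARQLExecutable ;\n",
    "  spex:describe \"DESCRIBE <http://example.org/x>\" .\n"))
  expect_equal(desc$kind, "describe")
  ask <- parse_example(paste0(
    "@prefix sh: <http://www.w3.org/ns/shacl#> .\n",
    "<http://e/2> sh:ask \"ASK { ?s ?p ?o }\" .\n"))
  expect_equal(ask$kind, "ask")
})

test_that("structural errors are classified", {
  expect_error(parse_example("not turtle at all {{{"), class = "example_turtle_error")
  expect_error(parse_example(
    "@prefix sh: <http://www.w3.org/ns/shacl#> . <http://e/1> a sh:SPARQLExecutable ."),
    class = "example_missing_query")
  expect_error(parse_example(paste0(
    "@prefix sh: <http://www.w3.org/ns/shacl#> .\n",
    "<http://e/1> sh:select \"SELECT * WHERE {}\" .\n",
    "<http://e/2> sh:select \"SELECT * WHERE {}\" .\n")),
    class = "example_structure_error")
  # one subject, two query properties: an error, not a multi-query document
  expect_error(parse_example(paste0(
    "@prefix sh: <http://www.w3.org/ns/shacl#> .\n",
    "<http://e/1> sh:select \"SELECT * WHERE {}\" ; sh:ask \"ASK {}\" .\n")),
    class = "example_structure_error")
})

test_that("serialize/parse round trip is graph-isomorphic", {
  doc <- parse_example(taxa_example_ttl())
  out <- serialize_example(doc)
  g1 <- parse_rdf(out, bnode_prefix = "a")
  g2 <- parse_rdf(serialize_example(parse_example(out)), bnode_prefix = "b")
  expect_true(graphs_isomorphic(g1, g2))
  # and the serialization is isomorphic to the original document's graph
  expect_true(graphs_isomorphic(parse_rdf(taxa_example_ttl(), bnode_prefix = "o"), g1))
})

test_that("a describe example serializes with spex:describe and a single type", {
  doc <- example_document(
    id = "http://e/d1", kind = "describe", query = "DESCRIBE <http://example.org/x>",
    comments = c(en = "Describe a thing"), targets = "https://sparql.uniprot.org/sparql/")
  out <- serialize_example(doc)
  expect_match(out, "spex:describe", fixed = TRUE)
  g <- parse_rdf(out)
  types <- g$o[g$p == rdf_iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")]
  expect_equal(types, rdf_iri("http://www.w3.org/ns/shacl#SPARQLExecutable"))
})

test_that("multilingual comments survive the round trip as a multiset", {
  doc <- example_document(
    id = "http://e/m1", kind = "select", query = "SELECT * WHERE { ?s ?p ?o }",
    comments = data.frame(text = c("All the data", "Toutes les donnees"),
                          lang = c("en", "fr"), stringsAsFactors = FALSE),
    targets = "https://www.bgee.org/sparql/")
  back <- parse_example(serialize_example(doc))
  expect_setequal(paste(back$comments$text, back$comments$lang),
                  paste(doc$comments$text, doc$comments$lang))
})

test_that("serialization is refused with the violated invariant named", {
  doc <- example_document(id = "http://e/x", kind = "select",
                          query = "SELECT * WHERE { ?s ?p ?o }",
                          comments = c(en = "q"), targets = character(0))
  expect_error(serialize_example(doc), "target", class = "example_invalid")
  doc2 <- example_document(id = NA_character_, kind = "select",
                           query = "SELECT * WHERE { ?s ?p ?o }",
                           comments = c(en = "q"), targets = "https://e.org/sparql/")
  expect_error(serialize_example(doc2), "identifier", class = "example_invalid")
  doc3 <- example_document(id = "http://e/x", kind = "select",
                           query = "SELECT * WHERE { ?s ?p ?o }",
                           comments = "untagged question", targets = "https://e.org/sparql/")
  expect_error(serialize_example(doc3), "language tag", class = "example_invalid")
})

test_that("collections load per resource folder with shared prefix resolution", {
  root <- tempfile("coll")
  for (res in c("bgee", "uniprot")) dir.create(file.path(root, res), recursive = TRUE)
  mk <- function(res, i, ns_file = TRUE) {
    doc <- example_document(
      id = sprintf("https://example.org/%s/%03d", res, i), kind = "select",
      query = "SELECT ?s WHERE { ?s a toy:Thing }",
      comments = c(en = sprintf("Example %d from %s", i, res)),
      targets = "https://example.org/sparql/",
      prefixes = prefix_map(), has_prefix_node = TRUE)
    writeLines(serialize_example(doc), file.path(root, res, sprintf("%03d.ttl", i)))
  }
  for (i in 1:3) mk("bgee", i)
  for (i in 1:2) mk("uniprot", i)
  writeLines(paste0(
    "PREFIX sh: <http://www.w3.org/ns/shacl#>\nPREFIX xsd: <http://www.w3.org/2001/XMLSchema#>\n",
    "_:sparql_examples_prefixes sh:declare [ sh:prefix \"toy\" ; ",
    "sh:namespace \"https://example.org/toy/\"^^xsd:anyURI ] ."),
    file.path(root, "bgee", "prefixes.ttl"))
  coll <- load_collection(root)
  expect_length(coll$examples, 5L)
  expect_equal(sort(unique(coll$resources)), c("bgee", "uniprot"))
  expect_equal(sum(coll$resources == "bgee"), 3L)
  # prefixes.ttl consumed for resolution, not an example; bgee docs got "toy"
  bgee_doc <- coll$examples[[which(coll$resources == "bgee")[1]]]
  expect_equal(unname(bgee_doc$prefixes[["toy"]]), "https://example.org/toy/")
  uni_doc <- coll$examples[[which(coll$resources == "uniprot")[1]]]
  expect_length(uni_doc$prefixes, 0L)
})

test_that("an empty folder yields an empty collection", {
  root <- tempfile("empty")
  dir.create(root)
  coll <- load_collection(root)
  expect_length(coll$examples, 0L)
})

test_that("duplicate identifiers raise a collection error naming both files", {
  root <- tempfile("dup")
  dir.create(file.path(root, "res"), recursive = TRUE)
  doc <- example_document(id = "https://example.org/dup/001", kind = "select",
                          query = "SELECT * WHERE { ?s ?p ?o }",
                          comments = c(en = "q"), targets = "https://e.org/sparql/")
  writeLines(serialize_example(doc), file.path(root, "res", "a.ttl"))
  writeLines(serialize_example(doc), file.path(root, "res", "b.ttl"))
  err <- tryCatch(load_collection(root), error = function(e) e)
  expect_s3_class(err, "example_collection_error")
  expect_match(conditionMessage(err), "a.ttl")
  expect_match(conditionMessage(err), "b.ttl")
  # keep mode records the duplicate for validation instead
  coll <- load_collection(root, on_duplicate = "keep")
  expect_equal(nrow(coll$duplicates), 1L)
})

test_that("collection loading does not depend on file creation order", {
  mk_root <- function(order) {
    root <- tempfile("ord")
    dir.create(file.path(root, "res"), recursive = TRUE)
    for (i in order) {
      doc <- example_document(id = sprintf("https://example.org/o/%03d", i), kind = "select",
                              query = "SELECT * WHERE { ?s ?p ?o }",
                              comments = c(en = sprintf("q%d", i)),
                              targets = "https://e.org/sparql/")
      writeLines(serialize_example(doc), file.path(root, "res", sprintf("%03d.ttl", i)))
    }
    root
  }
  c1 <- load_collection(mk_root(c(1, 2, 3)))
  c2 <- load_collection(mk_root(c(3, 1, 2)))
  expect_equal(vapply(c1$examples, function(d) d$id, character(1)),
               vapply(c2$examples, function(d) d$id, character(1)))
})
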