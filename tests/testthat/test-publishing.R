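# Publishing: named graph IRIs, merged graphs, query search, JSON export.

test_that("the well-known named graph IRI joins with correct slash handling", {
  expect_equal(named_graph_iri("https://sparql.uniprot.org/sparql/"),
               "https://sparql.uniprot.org/sparql/.well-known/sparql-examples")
  expect_equal(named_graph_iri("https://example.org/sparql"),
               "https://example.org/sparql/.well-known/sparql-examples")
  expect_error(named_graph_iri("sparql/"), "absolute")
})

test_that("merging selects exactly the examples targeting the endpoint", {
  coll <- make_clean_collection(n = 10L, seed = 17L)
  ep <- "https://sparql.uniprot.org/sparql/"
  expected <- sum(vapply(coll$examples, function(d) ep %in% d$targets, logical(1)))
  merged <- merge_collection(coll, ep)
  expect_equal(merged$n_examples, expected)
  expect_equal(merged$graph_iri, named_graph_iri(ep))
  # every example subject in the merged graph has schema:target = endpoint
  tgt <- merged$graph[merged$graph$p == rdf_iri("https://schema.org/target"), ]
  subj_with_ep <- unique(tgt$s[tgt$o == rdf_iri(ep)])
  qprops <- merged$graph$s[merged$graph$p %in%
    rdf_iri(c("http://www.w3.org/ns/shacl#select", "http://www.w3.org/ns/shacl#ask",
              "https://purl.expasy.org/sparql-examples/ontology#describe"))]
  expect_setequal(unique(qprops), subj_with_ep)
  # serializes to a single valid Turtle document
  ttl <- serialize_merged_graph(merged)
  expect_true(graphs_isomorphic(parse_rdf(ttl, bnode_prefix = "rt"), merged$graph))
})

test_that("a multi-target example appears in every matching merge", {
  doc <- example_document(id = "http://e/mt", kind = "select",
                          query = "SELECT * WHERE { ?s ?p ?o }", comments = c(en = "q"),
                          targets = c("https://a.org/sparql/", "https://b.org/sparql/"))
  coll <- example_collection(list(doc), "res")
  expect_equal(merge_collection(coll, "https://a.org/sparql/")$n_examples, 1L)
  expect_equal(merge_collection(coll, "https://b.org/sparql/")$n_examples, 1L)
})

test_that("merged-graph counts partition the collection by target", {
  coll <- make_clean_collection(n = 12L, seed = 19L)
  endpoints <- unique(unlist(lapply(coll$examples, function(d) d$targets)))
  merged_total <- sum(vapply(endpoints, function(ep)
    suppressWarnings(merge_collection(coll, ep)$n_examples), integer(1)))
  target_slots <- sum(vapply(coll$examples, function(d) length(d$targets), integer(1)))
  expect_equal(merged_total, target_slots)
  single_target <- vapply(coll$examples, function(d) length(d$targets) == 1L, logical(1))
  expect_gte(sum(single_target), 1L)  # the partition property is non-vacuous
})

test_that("an empty merge warns and produces an empty graph", {
  coll <- example_collection(list(), character(0))
  expect_warning(merged <- merge_collection(coll, "https://nobody.org/sparql/"),
                 "no examples")
  expect_equal(nrow(merged$graph), 0L)
})

test_that("keyword search over the merged graph matches the question substring", {
  coll <- make_clean_collection(n = 12L, seed = 23L)
  ep <- "https://sparql.uniprot.org/sparql/"
  merged <- merge_collection(coll, ep)
  hits <- query_for_queries(merged, "species")
  expected_ids <- vapply(coll$examples, function(d) d$id, character(1))[
    vapply(coll$examples, function(d)
      ep %in% d$targets && d$kind == "select" && any(grepl("species", d$comments$text, fixed = TRUE)),
      logical(1))]
  expect_setequal(unique(hits$example), expected_ids)
  # case-sensitive by default, flag for case-insensitive
  expect_equal(nrow(query_for_queries(merged, "SPECIES")), 0L)
  expect_equal(unique(query_for_queries(merged, "SPECIES", ignore_case = TRUE)$example),
               unique(hits$example))
})

test_that("an empty keyword returns every SELECT example", {
  coll <- make_clean_collection(n = 10L, seed = 29L)
  ep <- "https://sparql.uniprot.org/sparql/"
  merged <- merge_collection(coll, ep)
  all_rows <- query_for_queries(merged, "")
  n_select <- sum(vapply(coll$examples, function(d)
    ep %in% d$targets && d$kind == "select", logical(1)))
  expect_equal(length(unique(all_rows$example)), n_select)
  expect_equal(nrow(query_for_queries(merged, "no such phrase anywhere")), 0L)
})

test_that("every query text in the export re-parses", {
  coll <- make_clean_collection(n = 8L, seed = 31L)
  recs <- jsonlite::fromJSON(export_bioquery_json(coll), simplifyVector = FALSE)
  for (r in recs) expect_s3_class(parse_sparql(r$query), "sparql_query")
})

test_that("the Bio-Query export carries categories and label fallbacks", {
  docs <- list(
    example_document(id = "http://e/2", kind = "select", query = "SELECT * WHERE { ?s ?p ?o }",
                     comments = data.frame(text = c("hola", "hello"), lang = c("es", "en"),
                                           stringsAsFactors = FALSE),
                     targets = "https://a.org/sparql/"),
    example_document(id = "http://e/1", kind = "select", query = "SELECT * WHERE { ?s ?p ?o }",
                     comments = data.frame(text = "seulement en francais", lang = "fr",
                                           stringsAsFactors = FALSE),
                     targets = "https://a.org/sparql/"))
  coll <- example_collection(docs, c("bgee", "oma"))
  recs <- jsonlite::fromJSON(export_bioquery_json(coll), simplifyVector = FALSE)
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("http://e/1", "http://e/2"))  # id order
  expect_equal(recs[[2]]$label, "hello")                 # English preferred
  expect_equal(recs[[1]]$label, "seulement en francais") # fallback: first question
  expect_setequal(vapply(recs, `[[`, character(1), "category"), c("bgee", "oma"))
  expect_equal(export_bioquery_json(example_collection(list(), character(0))),
               structure("[]", class = "json"), ignore_attr = TRUE)
})

test_that("a five-example two-resource fixture exports five records, two categories", {
  root <- tempfile("bq")
  spec <- fixture_spec(n_examples = 5L, resources = c("bgee", "uniprot"),
                       endpoints = c("https://www.bgee.org/sparql/",
                                     "https://sparql.uniprot.org/sparql/"),
                       seed = 37L)
  generate_fixture_collection(spec, root)
  coll <- load_collection(root)
  recs <- jsonlite::fromJSON(export_bioquery_json(coll), simplifyVector = FALSE)
  expect_length(recs, 5L)
  expect_setequal(unique(vapply(recs, `[[`, character(1), "category")), c("bgee", "uniprot"))
})
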