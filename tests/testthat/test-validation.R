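# Validation rules, reports, and the execution probe.

test_that("a conforming example passes with zero errors", {
  rep <- validate_example(parse_example(taxa_example_ttl()))
  expect_true(rep$passed)
  expect_equal(sum(rep$issues$severity == "error"), 0L)
})

test_that("each mandatory-field violation yields its dedicated code", {
  doc <- parse_example(taxa_example_ttl())
  no_comment <- doc; no_comment$comments <- doc$comments[0, ]
  expect_true("MISSING_COMMENT" %in% validate_example(no_comment)$issues$code)
  no_target <- doc; no_target$targets <- character(0)
  expect_true("MISSING_TARGET" %in% validate_example(no_target)$issues$code)
  no_type <- doc; no_type$declared_types <- character(0)
  expect_true("MISSING_TYPE" %in% validate_example(no_type)$issues$code)
  no_id <- doc; no_id$id <- NA_character_
  expect_true("MISSING_ID" %in% validate_example(no_id)$issues$code)
  no_lang <- doc; no_lang$comments$lang <- NA_character_
  expect_true("MISSING_LANGUAGE_TAG" %in% validate_example(no_lang)$issues$code)
  broken <- doc; broken$query <- "SELEC T ?x WHERE { ?x ?p ?o }"
  expect_true("SYNTAX_ERROR" %in% validate_example(broken)$issues$code)
})

test_that("type/query consistency is checked both ways", {
  doc <- parse_example(taxa_example_ttl())
  wrong_type <- doc
  wrong_type$declared_types <- c("http://www.w3.org/ns/shacl#SPARQLAskExecutable",
                                 "http://www.w3.org/ns/shacl#SPARQLExecutable")
  expect_true("TYPE_QUERY_MISMATCH" %in% validate_example(wrong_type)$issues$code)
  wrong_text <- doc
  wrong_text$query <- "ASK { ?s ?p ?o }"   # sh:select carrying an ASK query
  expect_true("TYPE_QUERY_MISMATCH" %in% validate_example(wrong_text)$issues$code)
  describe_with_subtype <- doc
  describe_with_subtype$kind <- "describe"
  describe_with_subtype$query <- "DESCRIBE <http://example.org/x>"
  expect_true("TYPE_QUERY_MISMATCH" %in% validate_example(describe_with_subtype)$issues$code)
})

test_that("federation declarations must match SERVICE usage", {
  doc <- parse_example(taxa_example_ttl())
  declared_not_federated <- doc
  declared_not_federated$federates_with <- "https://query.wikidata.org/sparql"
  rep <- validate_example(declared_not_federated)
  expect_false(rep$passed)
  expect_true("FEDERATED_WITHOUT_SERVICE" %in% rep$issues$code)
  # keyword-based declaration triggers the same rule
  keyword_declared <- doc
  keyword_declared$keywords <- c(doc$keywords, "federated")
  expect_true("FEDERATED_WITHOUT_SERVICE" %in% validate_example(keyword_declared)$issues$code)
  # the reverse direction is a warning, not an error
  service_undeclared <- doc
  service_undeclared$query <- paste0(
    "PREFIX up: <http://purl.uniprot.org/core/>\nSELECT ?taxon WHERE {\n",
    "  SERVICE <https://sparql.uniprot.org/sparql/> { ?taxon a up:Taxon }\n}")
  rep2 <- validate_example(service_undeclared)
  expect_true(rep2$passed)
  expect_true("UNDECLARED_FEDERATION" %in% rep2$issues$code)
  expect_equal(rep2$issues$severity[rep2$issues$code == "UNDECLARED_FEDERATION"], "warning")
})

test_that("validation is pure: identical input gives identical reports", {
  doc <- parse_example(taxa_example_ttl())
  doc$federates_with <- "https://query.wikidata.org/sparql"
  expect_identical(validate_example(doc), validate_example(doc))
})

test_that("collection validation unions per-example and collection rules", {
  coll <- make_clean_collection(n = 10L, seed = 3L)
  rep <- validate_collection(coll)
  expect_true(rep$passed)
  expect_equal(rep$examples_checked, 10L)
  empty <- example_collection(list(), character(0))
  rep0 <- validate_collection(empty)
  expect_true(rep0$passed)
  expect_equal(rep0$examples_checked, 0L)
})

test_that("the JSON report carries code, severity, subject, message, pointer", {
  doc <- parse_example(taxa_example_ttl())
  doc$targets <- character(0)
  json <- write_validation_report(validate_example(doc))
  parsed <- jsonlite::fromJSON(json)
  expect_false(parsed$passed)
  expect_true(all(c("code", "severity", "subject", "message", "pointer") %in%
                  names(parsed$issues)))
})

test_that("probe rewriting caps the result limit at exactly one", {
  rw <- rewrite_query_limit("SELECT ?s WHERE { ?s ?p ?o } LIMIT 500")
  expect_equal(rw$effective_limit, 1L)
  expect_match(rw$query, "LIMIT 1", fixed = TRUE)
  expect_false(grepl("500", rw$query))
  rw2 <- rewrite_query_limit("SELECT ?s WHERE { ?s ?p ?o }")
  expect_match(rw2$query, "LIMIT 1$")
  # a subquery limit is not the query's limit and must not be touched
  rw3 <- rewrite_query_limit(
    "SELECT ?s WHERE { { SELECT ?s WHERE { ?s ?p ?o } LIMIT 40 } }")
  expect_true(grepl("LIMIT 40", rw3$query, fixed = TRUE))
  expect_match(rw3$query, "LIMIT 1$")
  # LIMIT 0 is kept and flagged
  rw4 <- rewrite_query_limit("SELECT ?s WHERE { ?s ?p ?o } LIMIT 0")
  expect_true(rw4$kept_zero)
  expect_equal(rw4$effective_limit, 0L)
})

test_that("the probe rewrite only touches the limit", {
  q <- "SELECT ?s # keep this comment\nWHERE { ?s ?p ?o . }\nLIMIT 500"
  rw <- rewrite_query_limit(q)
  expect_equal(sub("LIMIT 1", "LIMIT 500", rw$query, fixed = TRUE), q)
})

test_that("probing reports ok/empty/failed outcomes", {
  doc <- parse_example(taxa_example_ttl(),
                       extra_prefixes = c(up = "http://purl.uniprot.org/core/"))
  graph <- rdf_graph(rdf_iri("http://t/x"),
                     rdf_iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"),
                     rdf_iri("http://purl.uniprot.org/core/Taxon"))
  res <- probe_example(doc, graph)
  expect_equal(res$status, "ok")
  expect_match(res$rewritten_query, "LIMIT 1")
  expect_equal(probe_example(doc, rdf_graph())$status, "empty")
  off <- probe_example(doc, "https://sparql.uniprot.org/sparql/", network_allowed = FALSE)
  expect_equal(off$status, "failed")
  expect_equal(off$reason, "network disabled")
  update_doc <- example_document(id = "http://e/u", kind = "update",
                                 query = "DELETE WHERE { ?s ?p ?o }",
                                 comments = c(en = "q"), targets = "https://e.org/sparql/")
  expect_error(probe_example(update_doc, graph), "refusing")
})

test_that("ASK probes run unchanged", {
  doc <- example_document(id = "http://e/a", kind = "ask",
                          query = "ASK { ?s ?p ?o }",
                          comments = c(en = "anything?"), targets = "https://e.org/sparql/")
  graph <- rdf_graph(rdf_iri("http://t/s"), rdf_iri("http://t/p"), rdf_iri("http://t/o"))
  res <- probe_example(doc, graph)
  expect_equal(res$status, "ok")
  expect_equal(res$rewritten_query, doc$query)
})
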