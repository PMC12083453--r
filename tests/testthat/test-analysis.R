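# Complexity metrics: triple-pattern counting and collection statistics.

test_that("the printed worked examples count as documented", {
  expect_equal(analyze_query(taxa_example_query())$triple_pattern_count, 1L)
  m2 <- analyze_query(retrieval_pattern_query())
  expect_equal(m2$triple_pattern_count, 2L)
  expect_true(m2$uses_filter)
  expect_false(m2$federated)
  m3 <- analyze_query("SELECT (COUNT(?x) AS ?n) WHERE { ?x a <http://e/C> }")
  expect_equal(unname(m3$aggregate_counts["COUNT"]), 1L)
  expect_equal(m3$triple_pattern_count, 1L)
})

test_that("counting follows the declared convention across pattern contexts", {
  q <- paste0(
    "PREFIX x: <http://x/>\nSELECT ?a WHERE {\n",
    "  ?a x:p1 ?b .\n",                       # 1
    "  OPTIONAL { ?b x:p2 ?c }\n",            # 1
    "  { ?a x:p3 ?d } UNION { ?a x:p4 ?d }\n",# 2
    "  MINUS { ?a x:p5 ?e }\n",               # 1
    "  SERVICE <http://r/sparql> { ?a x:p6 ?f }\n",  # 1
    "  { SELECT ?a WHERE { ?a x:p7 ?g . ?g x:p8 ?h } }\n",  # 2
    "  FILTER EXISTS { ?a x:p9 ?i }\n",       # 1
    "  VALUES ?v { 1 2 3 }\n",                # 0
    "}")
  expect_equal(analyze_query(q)$triple_pattern_count, 9L)
})

test_that("property paths decompose per the sequence-length rule", {
  x <- "PREFIX x: <http://x/>\n"
  expect_equal(analyze_query(paste0(x, "SELECT ?d WHERE { ?p x:a/x:b ?d }"))$triple_pattern_count, 2L)
  expect_equal(analyze_query(paste0(x, "SELECT ?d WHERE { ?p x:a/x:b/x:c ?d }"))$triple_pattern_count, 3L)
  expect_equal(analyze_query(paste0(x, "SELECT ?d WHERE { ?p ^x:a ?d }"))$triple_pattern_count, 1L)
  expect_equal(analyze_query(paste0(x, "SELECT ?d WHERE { ?p (x:a|x:b) ?d }"))$triple_pattern_count, 1L)
  expect_equal(analyze_query(paste0(x, "SELECT ?d WHERE { ?p x:a* ?d }"))$triple_pattern_count, 1L)
  expect_equal(analyze_query(paste0(x, "SELECT ?d WHERE { ?p x:a/(x:b|x:c) ?d }"))$triple_pattern_count, 2L)
})

test_that("appending one basic pattern increases the count by exactly one", {
  base <- "PREFIX x: <http://x/>\nSELECT * WHERE { ?a x:p ?b . "
  extras <- c("", "?b x:q ?c . ", "?c x:r/x:s ?d . ")
  q <- base
  prev <- NA_integer_
  for (i in seq_along(extras)) {
    q <- paste0(q, extras[i])
    cnt <- analyze_query(paste0(q, "}"))$triple_pattern_count
    if (i == 2L) expect_equal(cnt, prev + 1L)
    prev <- cnt
  }
})

test_that("counts match the independent brute-force oracle on generated queries", {
  qs <- generate_fixture_queries(120L, seed = 11L, fraction_federated = 0.15)
  for (i in seq_len(nrow(qs))) {
    expect_equal(analyze_query(qs$query[i])$triple_pattern_count,
                 oracle_tp_count(qs$query[i]), info = qs$template[i])
    expect_equal(analyze_query(qs$query[i])$triple_pattern_count, qs$tp[i],
                 info = qs$template[i])
  }
})

test_that("collection statistics aggregate per endpoint with exact means", {
  docs <- lapply(1:3, function(i) {
    tps <- list(
      "SELECT * WHERE { ?a <http://x/p> ?b . ?b <http://x/q> ?c . ?c <http://x/r> ?d }",
      paste0("SELECT * WHERE { ", paste(sprintf("?v%d <http://x/p> ?w%d .", 1:5, 1:5),
                                        collapse = " "), " }"),
      paste0("SELECT * WHERE { ", paste(sprintf("?v%d <http://x/p> ?w%d .", 1:7, 1:7),
                                        collapse = " "), " }"))
    example_document(id = sprintf("http://e/%d", i), kind = "select", query = tps[[i]],
                     comments = c(en = sprintf("q%d", i)), targets = "https://e.org/sparql/")
  })
  coll <- example_collection(docs, rep("res", 3L))
  st <- collection_stats(coll)
  expect_equal(nrow(st), 1L)
  expect_equal(st$n_queries, 3L)
  expect_equal(st$mean_triple_patterns, 5.0)
})

test_that("a multi-target example contributes to every target row", {
  doc <- example_document(id = "http://e/mt", kind = "select",
                          query = "SELECT * WHERE { ?s ?p ?o }",
                          comments = c(en = "q"),
                          targets = c("https://a.org/sparql/", "https://b.org/sparql/"))
  st <- collection_stats(example_collection(list(doc), "res"))
  expect_equal(nrow(st), 2L)
  expect_equal(st$n_queries, c(1L, 1L))
})

test_that("query counts are conserved over the collection", {
  coll <- make_clean_collection(n = 12L, seed = 5L)
  st <- collection_stats(coll)
  n_target_slots <- sum(vapply(coll$examples, function(d) length(d$targets), integer(1)))
  expect_equal(sum(st$n_queries), n_target_slots)
  expect_equal(nrow(collection_stats(example_collection(list(), character(0)))), 0L)
})

test_that("unanalyzable examples are excluded and reported", {
  bad <- example_document(id = "http://e/bad", kind = "select",
                          query = "SELEC T broken", comments = c(en = "q"),
                          targets = "https://e.org/sparql/")
  ok <- example_document(id = "http://e/ok", kind = "select",
                         query = "SELECT * WHERE { ?s ?p ?o }", comments = c(en = "q"),
                         targets = "https://e.org/sparql/")
  st <- collection_stats(example_collection(list(bad, ok), c("r", "r")))
  expect_equal(st$n_queries, 1L)
  expect_equal(attr(st, "excluded")$id, "http://e/bad")
})

test_that("stats export as TSV and JSON", {
  st <- collection_stats(make_clean_collection(n = 6L, seed = 9L))
  tsv <- tempfile(fileext = ".tsv")
  write_collection_stats(st, tsv, "tsv")
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(st))
  js <- tempfile(fileext = ".json")
  write_collection_stats(st, js, "json")
  expect_equal(nrow(jsonlite::fromJSON(js)), nrow(st))
})
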