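# SPARQL 1.1 compliance fixer.

toy6 <- function() {
  # six-triple fixture graph for semantic-equivalence checks
  a <- rdf_iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
  toy <- function(x) rdf_iri(paste0("https://example.org/toy/", x))
  ent <- function(x) rdf_iri(paste0("https://example.org/e/", x))
  rdf_graph(
    s = c(ent("t1"), ent("t1"), ent("t2"), ent("t2"), ent("p1"), ent("p1")),
    p = c(a, toy("name"), a, toy("name"), a, toy("organism")),
    o = c(toy("Taxon"), rdf_literal("one"), toy("Taxon"), rdf_literal("two"),
          toy("Protein"), ent("t1")))
}

test_that("missing prefixes are restored from the registry in first-use order", {
  q <- "SELECT ?taxon ?l WHERE { ?taxon a up:Taxon ; rdfs:label ?l . }"
  res <- add_missing_prefixes(q, prefix_registry())
  expect_true(res$changed)
  expect_equal(res$applied_fixes, c("PREFIX_ADDED(up)", "PREFIX_ADDED(rdfs)"))
  parsed <- parse_sparql(res$fixed_query)
  expect_equal(parsed$form, "select")
  # idempotent on the fixed output
  expect_false(add_missing_prefixes(res$fixed_query, prefix_registry())$changed)
})

test_that("the canonical example with its PREFIX line deleted is repaired", {
  q <- sub("PREFIX up: <http://purl.uniprot.org/core/>\n", "", taxa_example_query(), fixed = TRUE)
  expect_error(parse_sparql(q), class = "sparql_unknown_prefix")
  res <- add_missing_prefixes(q, prefix_registry(common = c(up = "http://purl.uniprot.org/core/")))
  expect_equal(res$applied_fixes, "PREFIX_ADDED(up)")
  expect_equal(parse_sparql(res$fixed_query)$form, "select")
})

test_that("an unregistered prefix is an error naming the label", {
  err <- tryCatch(add_missing_prefixes("SELECT ?s WHERE { ?s foo:bar ?o }",
                                       prefix_registry(common = c(rdf = "http://r/"))),
                  error = function(e) e)
  expect_s3_class(err, "fixer_unknown_prefix")
  expect_match(conditionMessage(err), "foo")
})

test_that("prefix-like text inside strings, IRIs and comments is ignored", {
  q <- paste0("PREFIX x: <http://x/>\n# note: not a prefix\n",
              "SELECT ?s WHERE { ?s x:p \"contains fake:prefix inside\" . ",
              "?s x:q <http://site.org/a:b> . }")
  expect_false(add_missing_prefixes(q, prefix_registry())$changed)
})

test_that("overlay registry entries shadow common entries", {
  reg <- prefix_registry(common = c(up = "http://purl.uniprot.org/core/"),
                         overlay = c(up = "http://project.org/up/"))
  res <- add_missing_prefixes("SELECT ?s WHERE { ?s a up:Taxon }", reg)
  expect_match(res$fixed_query, "http://project.org/up/", fixed = TRUE)
})

test_that("named subqueries are inlined with results identical to the standard form", {
  g <- toy6()
  vendor <- paste0(
    "PREFIX toy: <https://example.org/toy/>\n",
    "SELECT ?t ?n\n",
    "WITH { SELECT ?t WHERE { ?t a toy:Taxon } } AS %taxa\n",
    "WHERE { INCLUDE %taxa . ?t toy:name ?n }")
  standard <- paste0(
    "PREFIX toy: <https://example.org/toy/>\n",
    "SELECT ?t ?n\n",
    "WHERE { { SELECT ?t WHERE { ?t a toy:Taxon } } ?t toy:name ?n }")
  res <- rewrite_named_subqueries(vendor)
  expect_equal(res$applied_fixes, "NAMED_SUBQUERY_INLINED(taxa)")
  expect_equal(parse_sparql(res$fixed_query)$form, "select")
  expect_equal(rows_fingerprint(sparql_eval(res$fixed_query, g)),
               rows_fingerprint(sparql_eval(standard, g)))
})

test_that("multiple INCLUDEs duplicate the subselect", {
  vendor <- paste0(
    "PREFIX toy: <https://example.org/toy/>\n",
    "SELECT ?t\nWITH { SELECT ?t WHERE { ?t a toy:Taxon } } AS %taxa\n",
    "WHERE { { INCLUDE %taxa } UNION { INCLUDE %taxa } }")
  res <- rewrite_named_subqueries(vendor)
  expect_equal(lengths(regmatches(res$fixed_query,
                                  gregexpr("SELECT ?t WHERE", res$fixed_query, fixed = TRUE))), 2L)
  expect_equal(nrow(sparql_eval(res$fixed_query, toy6())), 4L)  # two branches x two taxa
})

test_that("named-subquery edge cases: no-op, undefined name, unused block", {
  clean <- "SELECT ?s WHERE { ?s ?p ?o }"
  expect_false(rewrite_named_subqueries(clean)$changed)
  expect_error(rewrite_named_subqueries("SELECT ?s WHERE { INCLUDE %missing }"),
               class = "fixer_undefined_subquery")
  expect_warning(
    res <- rewrite_named_subqueries(paste0(
      "SELECT ?s WITH { SELECT ?s WHERE { ?s ?p ?o } } AS %unused WHERE { ?s ?p ?o }")),
    "never included")
  expect_false(grepl("WITH", res$fixed_query, fixed = TRUE))
})

test_that("hint triples are stripped and results equal the clean query's", {
  g <- toy6()
  hinted <- paste0(
    "PREFIX toy: <https://example.org/toy/>\n",
    "PREFIX hint: <http://www.bigdata.com/queryHints#>\n",
    "SELECT ?t ?n WHERE {\n",
    "  hint:Query hint:optimizer \"None\" .\n",
    "  ?t a toy:Taxon ;\n    toy:name ?n .\n}")
  clean <- paste0(
    "PREFIX toy: <https://example.org/toy/>\n",
    "SELECT ?t ?n WHERE {\n  ?t a toy:Taxon ;\n    toy:name ?n .\n}")
  res <- strip_query_hints(hinted)
  expect_equal(res$applied_fixes, "HINT_REMOVED(1)")
  rows <- sparql_eval(res$fixed_query, g)
  expect_gt(nrow(rows), 0L)
  expect_equal(rows_fingerprint(rows), rows_fingerprint(sparql_eval(clean, g)))
})

test_that("hint predicates mixed into a statement are removed individually", {
  q <- paste0(
    "PREFIX toy: <https://example.org/toy/>\n",
    "PREFIX hint: <http://www.bigdata.com/queryHints#>\n",
    "SELECT ?t WHERE {\n",
    "  ?t a toy:Taxon ;\n    hint:rangeSafe \"true\" ;\n    toy:name ?n .\n}")
  res <- strip_query_hints(q)
  expect_equal(res$applied_fixes, "HINT_REMOVED(1)")
  m <- analyze_query(res$fixed_query)
  expect_equal(m$triple_pattern_count, 2L)
})

test_that("a query that is all hints is an error; hint-free queries are untouched", {
  all_hints <- paste0(
    "PREFIX hint: <http://www.bigdata.com/queryHints#>\n",
    "SELECT ?s WHERE { hint:Query hint:optimizer \"None\" . }")
  expect_error(strip_query_hints(all_hints), class = "fixer_all_hints")
  clean <- "SELECT ?s WHERE { ?s ?p ?o }"
  expect_false(strip_query_hints(clean)$changed)
})

test_that("the full pipeline applies fixes in order and is idempotent", {
  composite <- paste0(
    "SELECT ?t ?n\n",
    "WITH { SELECT ?t WHERE { ?t a toy:Taxon } } AS %taxa\n",
    "WHERE {\n  hint:Query hint:optimizer \"None\" .\n",
    "  INCLUDE %taxa .\n  ?t toy:name ?n .\n}")
  reg <- prefix_registry(overlay = c(toy = "https://example.org/toy/"))
  res <- fix_query(composite, registry = reg)
  codes <- sub("\\(.*", "", res$applied_fixes)
  expect_equal(unique(codes), c("PREFIX_ADDED", "NAMED_SUBQUERY_INLINED", "HINT_REMOVED"))
  expect_equal(parse_sparql(res$fixed_query)$form, "select")
  again <- fix_query(res$fixed_query, registry = reg)
  expect_false(again$changed)
  # semantics preserved on the fixture graph
  clean <- paste0(
    "PREFIX toy: <https://example.org/toy/>\n",
    "SELECT ?t ?n WHERE { { SELECT ?t WHERE { ?t a toy:Taxon } } ?t toy:name ?n }")
  expect_equal(rows_fingerprint(sparql_eval(res$fixed_query, toy6())),
               rows_fingerprint(sparql_eval(clean, toy6())))
})

test_that("clean template queries pass through the pipeline unchanged", {
  qs <- generate_fixture_queries(15L, seed = 8L)
  for (i in seq_len(nrow(qs))) {
    if (qs$kind[i] == "describe") next  # DESCRIBE <iri> has no prefixes to scan
    res <- fix_query(qs$query[i])
    expect_false(res$changed, info = qs$template[i])
  }
})

test_that("config files provide overlay prefixes and hint namespaces", {
  cfg <- tempfile(fileext = ".conf")
  writeLines(c("# project config",
               "prefix toy=https://example.org/toy/",
               "hint_namespace=http://vendor.example.org/hints#"), cfg)
  parsed <- read_fixer_config(cfg)
  expect_equal(unname(parsed$registry$overlay[["toy"]]), "https://example.org/toy/")
  expect_equal(parsed$hint_namespaces, "http://vendor.example.org/hints#")
  expect_error(read_fixer_config({
    f <- tempfile(); writeLines("nonsense line", f); f
  }), "unrecognized")
})
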