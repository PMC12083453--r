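# VoID generation, autocomplete suggestions, compliance checking.

taxon_toy_graph <- function() {
  a <- rdf_iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
  label <- rdf_iri("http://www.w3.org/2000/01/rdf-schema#label")
  taxon <- rdf_iri("https://example.org/toy/Taxon")
  subs <- rdf_iri(paste0("https://example.org/e/T", 1:3))
  rdf_graph(s = c(subs, subs), p = c(rep(a, 3), rep(label, 3)),
            o = c(rep(taxon, 3), rdf_literal(paste0("t", 1:3))))
}

test_that("partitions on the three-taxon toy graph count exactly", {
  v <- generate_void(taxon_toy_graph(), "https://example.org/dataset")
  expect_equal(v$total_triples, 6L)
  expect_equal(v$class_partitions$class, "https://example.org/toy/Taxon")
  expect_equal(v$class_partitions$entities, 3L)
  pp <- v$property_partitions
  expect_setequal(pp$property, c("http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
                                 "http://www.w3.org/2000/01/rdf-schema#label"))
  expect_equal(sort(pp$triples), c(3L, 3L))
  expect_equal(sum(pp$triples), v$total_triples)
})

test_that("an empty dataset yields all-zero partitions", {
  v <- generate_void(rdf_graph(), "https://example.org/empty")
  expect_equal(v$total_triples, 0L)
  expect_equal(nrow(v$class_partitions), 0L)
  expect_equal(nrow(v$property_partitions), 0L)
  expect_equal(nrow(v$linkage), 0L)
})

test_that("untyped subjects produce linkage rows with the unknown-class marker", {
  g <- rdf_graph(s = rep(rdf_iri("https://example.org/e/u"), 2),
                 p = rdf_iri(paste0("https://example.org/toy/p", 1:2)),
                 o = c(rdf_literal("x"), rdf_iri("https://example.org/e/other")))
  v <- generate_void(g, "https://example.org/d")
  expect_equal(nrow(v$property_partitions), 2L)
  expect_setequal(v$linkage$subject_class, "unknown")
  expect_true("unknown" %in% v$linkage$object_class)  # untyped IRI object
  expect_true(any(grepl("XMLSchema#string", v$linkage$object_class)))
})

test_that("object classes come from types, datatypes and language tags", {
  a <- rdf_iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
  g <- rdf_graph(
    s = rdf_iri(c("http://e/s", "http://e/s", "http://e/s", "http://e/o")),
    p = c(a, rdf_iri("http://e/knows"), rdf_iri("http://e/label"), a),
    o = c(rdf_iri("http://e/Person"), rdf_iri("http://e/o"),
          '"hi"@en', rdf_iri("http://e/Person")))
  v <- generate_void(g, "http://e/d")
  link <- v$linkage[v$linkage$property == "http://e/knows", ]
  expect_equal(link$object_class, "http://e/Person")
  lab <- v$linkage[v$linkage$property == "http://e/label", ]
  expect_equal(lab$object_class, "http://www.w3.org/1999/02/22-rdf-syntax-ns#langString")
})

test_that("property counts are conserved and linkage is bounded on random graphs", {
  for (seed in 1:40) {
    g <- random_toy_graph(seed)
    v <- generate_void(g, "https://example.org/d")
    # independent counting walk
    expect_equal(sum(v$property_partitions$triples), nrow(g), info = seed)
    indep <- table(g$p)
    for (k in seq_len(nrow(v$property_partitions)))
      expect_equal(v$property_partitions$triples[k],
                   unname(indep[[rdf_iri(v$property_partitions$property[k])]]), info = seed)
    # each linkage row's count never exceeds its property partition count
    for (k in seq_len(nrow(v$linkage))) {
      cap <- v$property_partitions$triples[
        v$property_partitions$property == v$linkage$property[k]]
      expect_lte(v$linkage$triples[k], cap)
    }
    # entity counts are distinct typed subjects
    a <- rdf_iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
    for (k in seq_len(nrow(v$class_partitions)))
      expect_equal(v$class_partitions$entities[k],
                   length(unique(g$s[g$p == a & g$o == rdf_iri(v$class_partitions$class[k])])),
                   info = seed)
  }
})

test_that("VoID serialization is valid Turtle with the expected vocabulary", {
  v <- generate_void(taxon_toy_graph(), "https://example.org/dataset")
  ttl <- serialize_void(v)
  g <- parse_rdf(ttl)
  void <- function(x) rdf_iri(paste0("http://rdfs.org/ns/void#", x))
  expect_true(rdf_iri("https://example.org/dataset") %in% g$s)
  expect_equal(sum(g$p == void("classPartition")), 1L)
  expect_equal(sum(g$p == void("propertyPartition")), 4L)  # 2 global + 2 linkage
  expect_equal(literal_value(g$o[g$p == void("triples") & g$s == rdf_iri("https://example.org/dataset")]), "6")
})

test_that("predicate suggestions are scoped to the focus class and sound", {
  v <- generate_void(taxon_toy_graph(), "https://example.org/d")
  s <- suggest_completions(v, focus_class = "https://example.org/toy/Taxon")
  expect_setequal(s$iri, c("http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
                           "http://www.w3.org/2000/01/rdf-schema#label"))
  expect_false(attr(s, "unscoped"))
  expect_equal(s$curie[s$iri == "http://www.w3.org/2000/01/rdf-schema#label"], "rdfs:label")
  # soundness on random graphs: every suggested property occurs with the class
  for (seed in 1:10) {
    g <- random_toy_graph(seed + 100)
    vv <- generate_void(g, "https://example.org/d")
    a <- rdf_iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
    for (cl in vv$class_partitions$class) {
      sugg <- suggest_completions(vv, focus_class = cl)
      typed_subjects <- g$s[g$p == a & g$o == rdf_iri(cl)]
      for (p in sugg$iri)
        expect_true(any(g$p == rdf_iri(p) & g$s %in% typed_subjects),
                    info = paste(seed, cl, p))
    }
  }
})

test_that("partial input filters and ranking is deterministic", {
  v <- generate_void(taxon_toy_graph(), "https://example.org/d")
  lab <- suggest_completions(v, focus_class = "https://example.org/toy/Taxon", partial = "lab")
  expect_equal(lab$iri, "http://www.w3.org/2000/01/rdf-schema#label")
  expect_identical(suggest_completions(v, focus_class = "https://example.org/toy/Taxon"),
                   suggest_completions(v, focus_class = "https://example.org/toy/Taxon"))
  # descending count, lexicographic tie-break
  g <- generate_toy_dataset(4L, 6L, seed = 3L)
  vv <- generate_void(g, "https://example.org/d")
  s <- suggest_completions(vv, focus_class = NULL)
  expect_true(attr(s, "unscoped"))
  expect_true(all(diff(s$count) <= 0))
  ties <- split(s$iri, s$count)
  for (grp in ties) expect_equal(grp, sort(grp))
  # class-position suggestions list the class partitions
  cls <- suggest_completions(vv, position = "class")
  expect_setequal(cls$iri, vv$class_partitions$class)
})

test_that("compliance checking reports both checks with concrete suggestions", {
  coll <- make_clean_collection(n = 6L, seed = 41L)
  ep <- "https://sparql.uniprot.org/sparql/"
  merged <- merge_collection(coll, ep)
  exdump <- merged$graph
  exdump$g <- merged$graph_iri
  voidg <- parse_rdf(serialize_void(generate_void(generate_toy_dataset(), "http://e/d")))
  full <- rbind(as.data.frame(exdump), as.data.frame(voidg))
  class(full) <- c("rdf_graph", "data.frame")
  ok <- check_metadata_compliance(full, ep)
  expect_true(ok$has_examples_graph)
  expect_true(ok$has_void)
  expect_length(ok$suggestions, 0L)
  expect_equal(ok$example_count, merged$n_examples)

  no_void <- check_metadata_compliance(exdump, ep)
  expect_false(no_void$has_void)
  expect_match(paste(no_void$suggestions, collapse = " "), "VoID")

  no_examples <- check_metadata_compliance(voidg, ep)
  expect_false(no_examples$has_examples_graph)
  expect_match(paste(no_examples$suggestions, collapse = " "), "named graph")
})

test_that("invalid examples in the dump are excluded from the count and flagged", {
  ep <- "https://sparql.uniprot.org/sparql/"
  good <- example_document(id = "http://e/good", kind = "select",
                           query = "SELECT * WHERE { ?s ?p ?o }", comments = c(en = "q"),
                           targets = ep)
  coll <- example_collection(list(good), "res")
  merged <- merge_collection(coll, ep)
  dump <- merged$graph
  # append a defective example (no comment) into the same named graph
  bad_s <- rdf_iri("http://e/bad")
  dump <- rbind(as.data.frame(dump), data.frame(
    s = bad_s, p = rdf_iri("http://www.w3.org/ns/shacl#select"),
    o = rdf_literal("SELECT * WHERE { ?s ?p ?o }"), g = NA_character_,
    stringsAsFactors = FALSE))
  dump$g <- merged$graph_iri
  class(dump) <- c("rdf_graph", "data.frame")
  rep <- check_metadata_compliance(dump, ep)
  expect_equal(rep$example_count, 1L)
  expect_match(paste(rep$suggestions, collapse = " "), "fail validation")
})
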