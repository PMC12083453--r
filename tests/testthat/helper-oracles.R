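# Shared fixtures and independent oracles.

taxa_example_ttl <- function() {
  path <- system.file("extdata", "examples", "uniprot", "001.ttl", package = "sparqlexamples")
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

taxa_example_query <- function() parse_example(taxa_example_ttl())$query

retrieval_pattern_query <- function() paste0(
  "PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>\n",
  "PREFIX sh: <http://www.w3.org/ns/shacl#>\n",
  "SELECT * WHERE {\n",
  "  ?ex sh:select ?query.\n",
  "  ?ex rdfs:comment ?question.\n",
  '  FILTER (contains(?question, "species"))\n}')

# ---------------------------------------------------------------------------
# Independent triple-pattern counting oracle: a brute-force recursive walk
# over the parsed algebra, written separately from the analyzer (different
# recursion shape: path counting by case analysis, pattern walk by
# accumulating a running total through explicit recursion).

oracle_path_count <- function(p) {
  if (is.character(p)) return(1L)
  if (p$op == "seq") {
    total <- 0L
    for (el in p$elts) total <- total + oracle_path_count(el)
    return(total)
  }
  if (p$op == "inv") return(oracle_path_count(p$elts[[1L]]))
  1L  # alt, mod, neg are non-decomposable
}

oracle_expr_count <- function(e) {
  if (!is.list(e)) return(0L)
  total <- 0L
  if (identical(e$type, "exists")) total <- total + oracle_group_count(e$group)
  for (part in e) {
    if (is.list(part)) {
      if (!is.null(part$type)) total <- total + oracle_expr_count(part)
      else for (sub in part) if (is.list(sub)) total <- total + oracle_expr_count(sub)
    }
  }
  total
}

oracle_group_count <- function(node) {
  if (is.null(node)) return(0L)
  total <- 0L
  if (node$type == "group") {
    for (el in node$elts) total <- total + oracle_group_count(el)
  } else if (node$type == "tp") {
    total <- total + oracle_path_count(node$p)
  } else if (node$type %in% c("optional", "minus", "nested", "service", "graph")) {
    total <- total + oracle_group_count(node$group)
  } else if (node$type == "union") {
    for (b in node$branches) total <- total + oracle_group_count(b)
  } else if (node$type == "subselect") {
    total <- total + oracle_query_count(node$query)
  } else if (node$type %in% c("filter", "bind")) {
    total <- total + oracle_expr_count(node$expr)
  }
  total
}

oracle_query_count <- function(q) {
  total <- oracle_group_count(q$where)
  for (p in q$projection) if (!is.null(p$expr)) total <- total + oracle_expr_count(p$expr)
  if (!is.null(q$having)) for (h in q$having) total <- total + oracle_expr_count(h)
  total
}

oracle_tp_count <- function(query_text) oracle_query_count(parse_sparql(query_text))

# ---------------------------------------------------------------------------
# Canonical row-multiset fingerprint for comparing SELECT results.

rows_fingerprint <- function(df) {
  if (is.logical(df)) return(as.character(df))
  if (!nrow(df)) return(character(0))
  cols <- sort(names(df))
  sort(apply(df[, cols, drop = FALSE], 1L, function(r)
    paste(paste0(cols, "=", ifelse(is.na(r), "~", r)), collapse = "|")))
}

# ---------------------------------------------------------------------------
# Independent SPARQL oracle: rdflib via the system python (used on tiny
# fixtures to cross-check the package's own engine).

rdflib_select <- function(ttl, query) {
  dir <- tempfile("rdflib")
  dir.create(dir)
  writeLines(ttl, file.path(dir, "data.ttl"))
  writeLines(query, file.path(dir, "query.rq"))
  script <- file.path(dir, "run.py")
  writeLines(c(
    "import json, sys",
    "import rdflib",
    sprintf("g = rdflib.Graph(); g.parse('%s', format='turtle')", file.path(dir, "data.ttl")),
    sprintf("q = open('%s').read()", file.path(dir, "query.rq")),
    "res = g.query(q)",
    "rows = []",
    "for row in res:",
    "    rows.append({str(v): (row[v].n3() if row[v] is not None else None) for v in res.vars})",
    "print(json.dumps(rows))"), script)
  out <- system2("python", script, stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

rdflib_fingerprint <- function(rows) {
  if (!length(rows)) return(character(0))
  sort(vapply(rows, function(r) {
    r <- r[!vapply(r, is.null, logical(1))]
    cols <- sort(names(r))
    paste(paste0(cols, "=", vapply(cols, function(c) r[[c]], character(1))), collapse = "|")
  }, character(1)))
}

# Small random RDF graph for VoID property tests.
random_toy_graph <- function(seed) {
  set.seed(seed)
  n_subj <- sample(3:10, 1L)
  classes <- paste0("https://example.org/toy/C", 1:3)
  props <- paste0("https://example.org/toy/p", 1:4)
  s <- character(0); p <- character(0); o <- character(0)
  subjects <- paste0("https://example.org/e/S", seq_len(n_subj))
  for (i in seq_len(n_subj)) {
    if (stats::runif(1) < 0.8)
      for (cl in sample(classes, sample(1:2, 1L))) {
        s <- c(s, rdf_iri(subjects[i]))
        p <- c(p, rdf_iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"))
        o <- c(o, rdf_iri(cl))
      }
    for (k in seq_len(sample(1:4, 1L))) {
      s <- c(s, rdf_iri(subjects[i]))
      p <- c(p, rdf_iri(sample(props, 1L)))
      o <- c(o, if (stats::runif(1) < 0.5) rdf_literal(paste0("v", k))
                else rdf_iri(sample(subjects, 1L)))
    }
  }
  rdf_graph(s, p, o)
}

make_clean_collection <- function(n = 10L, seed = 42L, dir = tempfile("fixcoll")) {
  spec <- fixture_spec(n_examples = n, seed = seed)
  generate_fixture_collection(spec, dir)
  load_collection(dir)
}
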