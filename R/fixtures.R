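# Deterministic synthetic fixtures: example collections over a toy
# UniProt-like vocabulary, optional defect injection, and a toy RDF dataset
# on which every clean fixture query returns at least one result.
#
# The query grammar is closed and enumerable (templates t01-t15 below, 0-8
# triple patterns, covering OPTIONAL/UNION/MINUS/FILTER/aggregates/property
# paths/subqueries/SERVICE), so independent brute-force oracles can be
# written against it.

TOY_NS <- "https://example.org/toy/"
TOY_TAXON_NS <- "https://example.org/taxon/"
TOY_PROTEIN_NS <- "https://example.org/protein/"
TOY_ANNOT_NS <- "https://example.org/annotation/"
FIXTURE_REMOTE_ENDPOINT <- "https://query.wikidata.org/sparql"

FIXTURE_ENDPOINTS <- c(
  bgee = "https://www.bgee.org/sparql/",
  uniprot = "https://sparql.uniprot.org/sparql/",
  oma = "https://sparql.omabrowser.org/sparql/")

fixture_prefix_header <- function() paste0(
  "PREFIX toy: <", TOY_NS, ">\n",
  "PREFIX rdfs: <", RDFS_NS, ">\n")

# Each template: kind, triple-pattern count under the package convention,
# whether it is federated, the question text, keywords, and the query text.
fixture_templates <- function() {
  h <- fixture_prefix_header()
  list(
    t01 = list(kind = "select", tp = 1L, federated = FALSE,
      question = "Select all taxa from the toy taxonomy",
      keywords = c("taxa"),
      query = paste0(h, "SELECT ?taxon\nWHERE {\n  ?taxon a toy:Taxon .\n}")),
    t02 = list(kind = "select", tp = 2L, federated = FALSE,
      question = "List all taxa with their labels",
      keywords = c("taxa", "labels"),
      query = paste0(h, "SELECT ?taxon ?name\nWHERE {\n  ?taxon a toy:Taxon ;\n    rdfs:label ?name .\n}")),
    t03 = list(kind = "select", tp = 2L, federated = FALSE,
      question = "Which species have a scientific name recorded?",
      keywords = c("species"),
      query = paste0(h, "SELECT ?taxon ?name\nWHERE {\n  ?taxon a toy:Taxon ;\n    toy:scientificName ?name .\n  FILTER (CONTAINS(?name, \"species\"))\n}")),
    t04 = list(kind = "select", tp = 3L, federated = FALSE,
      question = "List proteins with the label of their organism",
      keywords = c("proteins", "organisms"),
      query = paste0(h, "SELECT ?protein ?name\nWHERE {\n  ?protein a toy:Protein ;\n    toy:organism ?taxon .\n  ?taxon rdfs:label ?name .\n}")),
    t05 = list(kind = "select", tp = 3L, federated = FALSE,
      question = "List proteins and, when available, their annotations",
      keywords = c("proteins", "annotations"),
      query = paste0(h, "SELECT ?protein ?annot\nWHERE {\n  ?protein a toy:Protein ;\n    rdfs:label ?label .\n  OPTIONAL { ?protein toy:annotation ?annot }\n}")),
    t06 = list(kind = "select", tp = 2L, federated = FALSE,
      question = "Which diseases are proteins annotated with?",
      keywords = c("diseases"),
      query = paste0(h, "SELECT ?disease\nWHERE {\n  ?protein toy:annotation/toy:disease ?disease .\n}")),
    t07 = list(kind = "select", tp = 2L, federated = FALSE,
      question = "List every taxon or protein in the dataset",
      keywords = c("inventory"),
      query = paste0(h, "SELECT ?entity\nWHERE {\n  { ?entity a toy:Taxon }\n  UNION\n  { ?entity a toy:Protein }\n}")),
    t08 = list(kind = "select", tp = 1L, federated = FALSE,
      question = "How many proteins are in the dataset?",
      keywords = c("count", "proteins"),
      query = paste0(h, "SELECT (COUNT(?protein) AS ?n)\nWHERE {\n  ?protein a toy:Protein .\n}")),
    t09 = list(kind = "ask", tp = 1L, federated = FALSE,
      question = "Is there at least one taxon in the taxonomy?",
      keywords = c("taxa"),
      query = paste0(h, "ASK {\n  ?taxon a toy:Taxon .\n}")),
    t10 = list(kind = "describe", tp = 0L, federated = FALSE,
      question = "Describe the first taxon of the toy taxonomy",
      keywords = c("taxa"),
      query = paste0("DESCRIBE <", TOY_TAXON_NS, "T1>")),
    t11 = list(kind = "select", tp = 3L, federated = TRUE,
      question = "List proteins with the scientific species name of their organism",
      keywords = c("proteins", "species"),
      query = paste0(h, "SELECT ?protein ?name\nWHERE {\n  ?protein a toy:Protein ;\n    toy:organism ?taxon .\n  SERVICE <", FIXTURE_REMOTE_ENDPOINT, "> {\n    ?taxon toy:scientificName ?name\n  }\n}")),
    t12 = list(kind = "select", tp = 5L, federated = FALSE,
      question = "List annotated proteins with their label and organism label",
      keywords = c("proteins", "annotations"),
      query = paste0(h, "SELECT ?protein ?plabel ?tlabel\nWHERE {\n  ?protein a toy:Protein ;\n    rdfs:label ?plabel ;\n    toy:organism ?taxon ;\n    toy:annotation ?annot .\n  ?taxon rdfs:label ?tlabel .\n}")),
    t13 = list(kind = "select", tp = 8L, federated = FALSE,
      question = "Give the full annotation report for each protein",
      keywords = c("proteins", "report"),
      query = paste0(h, "SELECT ?protein ?plabel ?tlabel ?disease\nWHERE {\n  ?protein a toy:Protein ;\n    rdfs:label ?plabel ;\n    toy:organism ?taxon ;\n    toy:annotation ?annot .\n  ?annot a toy:Annotation ;\n    toy:disease ?disease .\n  ?taxon a toy:Taxon ;\n    rdfs:label ?tlabel .\n}")),
    t14 = list(kind = "select", tp = 2L, federated = FALSE,
      question = "List labels of the taxa found by a subquery",
      keywords = c("taxa", "subquery"),
      query = paste0(h, "SELECT ?name\nWHERE {\n  { SELECT ?taxon WHERE { ?taxon a toy:Taxon } }\n  ?taxon rdfs:label ?name .\n}")),
    t15 = list(kind = "select", tp = 2L, federated = FALSE,
      question = "Which taxa are not marked extinct?",
      keywords = c("taxa"),
      query = paste0(h, "SELECT ?taxon\nWHERE {\n  ?taxon a toy:Taxon .\n  MINUS { ?taxon toy:extinct ?flag }\n}")))
}

#' Specification of a synthetic fixture collection
#'
#' The defaults emulate a small multi-resource collection: three resources
#' with their endpoints, about one query in ten federated, English questions
#' with a French translation on a subset.
#'
#' @param n_examples Number of examples to generate.
#' @param resources Resource folder names.
#' @param endpoints One endpoint IRI per resource.
#' @param fraction_federated Proportion of federated examples (SERVICE +
#'   spex:federatesWith).
#' @param languages Language tags for the questions; the first is used for
#'   every example, any further ones are added on a subset.
#' @param defects Named integer vector: issue code -> number of examples to
#'   corrupt with that defect (see the validation module for codes).
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_examples = 20L, resources = names(FIXTURE_ENDPOINTS),
                         endpoints = unname(FIXTURE_ENDPOINTS),
                         fraction_federated = 0.1, languages = c("en", "fr"),
                         defects = integer(0), seed = 42L) {
  stopifnot(length(resources) == length(endpoints), n_examples >= 0L)
  if (fraction_federated < 0 || fraction_federated > 1) stop("fraction_federated must be in [0, 1]")
  defects <- defects[defects > 0L]
  if (length(defects)) {
    bad <- setdiff(names(defects), VALIDATION_CODES)
    if (length(bad)) stop("unknown defect code(s): ", paste(bad, collapse = ", "))
    if (sum(defects) > n_examples) stop("more defects requested than examples generated")
  }
  structure(list(n_examples = as.integer(n_examples), resources = resources,
                 endpoints = endpoints, fraction_federated = fraction_federated,
                 languages = languages, defects = defects, seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion", sample.kind = "Rejection")
}

# French sentence used for the second-language question.
fr_question <- function(q) paste0("(fr) ", q)

#' Generate fixture queries from the closed template grammar
#'
#' @param n Number of queries.
#' @param seed Integer seed.
#' @param fraction_federated Proportion drawn from the federated template.
#' @return data.frame: `template`, `query`, `kind`, `tp` (the generator's own
#'   triple-pattern count), `federated`.
#' @export
generate_fixture_queries <- function(n, seed = 42L, fraction_federated = 0.1) {
  fixture_seed(seed)
  tpl <- fixture_templates()
  fed_names <- names(tpl)[vapply(tpl, `[[`, logical(1), "federated")]
  plain_names <- setdiff(names(tpl), fed_names)
  n_fed <- round(n * fraction_federated)
  picks <- c(sample(fed_names, n_fed, replace = TRUE),
             sample(plain_names, n - n_fed, replace = TRUE))
  picks <- sample(picks, length(picks))   # interleave
  data.frame(template = picks,
             query = vapply(picks, function(t) tpl[[t]]$query, character(1)),
             kind = vapply(picks, function(t) tpl[[t]]$kind, character(1)),
             tp = vapply(picks, function(t) tpl[[t]]$tp, integer(1)),
             federated = vapply(picks, function(t) tpl[[t]]$federated, logical(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Defect injection by line surgery on the serialized Turtle. Every fixture
# document ends with the sh:prefixes line, so the deleted lines are always
# interior ";"-terminated lines and the file stays valid Turtle.
inject_defect <- function(ttl, code) {
  lines <- strsplit(ttl, "\n", fixed = TRUE)[[1]]
  switch(code,
    MISSING_COMMENT = lines <- lines[!grepl("rdfs:comment", lines, fixed = TRUE)],
    MISSING_TARGET = lines <- lines[!grepl("schema:target", lines, fixed = TRUE)],
    MISSING_TYPE = lines <- lines[!grepl("^    a sh:", lines)],
    MISSING_LANGUAGE_TAG = lines <- sub('(rdfs:comment ".*")@[A-Za-z-]+', "\\1", lines),
    TYPE_QUERY_MISMATCH = lines <- sub("SPARQLSelectExecutable", "SPARQLAskExecutable", lines, fixed = TRUE),
    SYNTAX_ERROR = lines <- sub("SELECT", "SELEC T", lines, fixed = TRUE),
    FEDERATED_WITHOUT_SERVICE = {
      lines <- c(paste0("@prefix spex: <", SPEX_NS, "> ."), lines)
      anchor <- grep("sh:prefixes _:sparql_examples_prefixes", lines, fixed = TRUE)[1L]
      lines <- append(lines, paste0("    spex:federatesWith <", FIXTURE_REMOTE_ENDPOINT, "> ;"),
                      after = anchor - 1L)
    },
    stop("defect code not injectable: ", code))
  paste(lines, collapse = "\n")
}

# Defects that need a plain SELECT, non-federated victim.
SELECT_ONLY_DEFECTS <- c("TYPE_QUERY_MISMATCH", "SYNTAX_ERROR", "FEDERATED_WITHOUT_SERVICE",
                         "MISSING_LANGUAGE_TAG")

#' Generate a synthetic example collection on disk
#'
#' Writes one Turtle file per example under per-resource folders (plus a
#' shared `prefixes.ttl` per resource), drawing queries from the closed
#' template grammar. Defects named in the fixture spec corrupt otherwise-valid files;
#' the manifest records exactly which file received which defect.
#'
#' @param spec A [fixture_spec()].
#' @param out_folder Output folder (created if needed).
#' @return The manifest, invisibly: list with `files` (data.frame: file,
#'   resource, id, template, kind, federated, tp, defects) and `spec`. Also
#'   written as `manifest.json` in `out_folder`.
#' @export
generate_fixture_collection <- function(spec, out_folder) {
  dir.create(out_folder, recursive = TRUE, showWarnings = FALSE)
  tpl <- fixture_templates()
  qs <- generate_fixture_queries(spec$n_examples, seed = spec$seed,
                                 fraction_federated = spec$fraction_federated)
  n <- nrow(qs)
  res_idx <- rep(seq_along(spec$resources), length.out = n)

  # assign defect victims: compatible, disjoint, deterministic
  victims <- stats::setNames(rep(NA_integer_, n), NULL)
  assignment <- list()
  taken <- logical(n)
  for (code in names(spec$defects)) {
    for (k in seq_len(spec$defects[[code]])) {
      need_select <- code %in% SELECT_ONLY_DEFECTS
      cand <- which(!taken & (!need_select | (qs$kind == "select" & !qs$federated)))
      if (!length(cand)) stop("cannot place defect ", code, ": no compatible example left")
      taken[cand[1L]] <- TRUE
      assignment[[length(assignment) + 1L]] <- list(index = cand[1L], code = code)
    }
  }
  defect_of <- character(n)
  for (a in assignment) defect_of[a$index] <- a$code

  toy_prefixes <- prefix_map(toy = TOY_NS, rdfs = RDFS_NS)
  rows <- list()
  second_lang <- if (length(spec$languages) > 1L) spec$languages[-1L] else character(0)
  for (i in seq_len(n)) {
    res <- spec$resources[res_idx[i]]
    endpoint <- spec$endpoints[res_idx[i]]
    targets <- endpoint
    if (i %% 7L == 0L && length(spec$endpoints) > 1L)
      targets <- c(targets, spec$endpoints[res_idx[i] %% length(spec$endpoints) + 1L])
    t <- tpl[[qs$template[i]]]
    comments <- data.frame(text = t$question, lang = spec$languages[1L], stringsAsFactors = FALSE)
    if (length(second_lang) && i %% 5L == 0L)
      comments <- rbind(comments, data.frame(text = fr_question(t$question), lang = second_lang[1L],
                                             stringsAsFactors = FALSE))
    keywords <- t$keywords
    fed <- character(0)
    if (qs$federated[i]) {
      keywords <- c(keywords, "federated")
      fed <- FIXTURE_REMOTE_ENDPOINT
    }
    doc <- example_document(
      id = paste0("https://example.org/.well-known/sparql-examples/", res, "/", sprintf("%03d", i)),
      kind = t$kind, query = t$query, comments = comments, targets = targets,
      keywords = keywords, federates_with = fed, prefixes = toy_prefixes,
      has_prefix_node = TRUE)
    ttl <- serialize_example(doc)
    if (nzchar(defect_of[i])) ttl <- inject_defect(ttl, defect_of[i])
    dir.create(file.path(out_folder, res), recursive = TRUE, showWarnings = FALSE)
    file <- file.path(out_folder, res, sprintf("%03d.ttl", i))
    writeLines(ttl, file)
    rows[[i]] <- data.frame(
      file = file, resource = res, id = doc$id, template = qs$template[i],
      kind = t$kind, federated = qs$federated[i], tp = qs$tp[i],
      defects = defect_of[i], targets = paste(targets, collapse = " "),
      question = t$question, stringsAsFactors = FALSE)
  }
  for (res in unique(spec$resources[res_idx])) {
    writeLines(c(
      paste0("PREFIX sh: <", SH_NS, ">"),
      paste0("PREFIX xsd: <", XSD, ">"),
      "",
      "_:sparql_examples_prefixes",
      paste0('    sh:declare [ sh:prefix "toy" ; sh:namespace "', TOY_NS, '"^^xsd:anyURI ] ;'),
      paste0('    sh:declare [ sh:prefix "rdfs" ; sh:namespace "', RDFS_NS, '"^^xsd:anyURI ] .')),
      file.path(out_folder, res, "prefixes.ttl"))
  }
  manifest <- list(files = if (length(rows)) do.call(rbind, rows)
                   else data.frame(), spec = unclass(spec))
  jsonlite::write_json(manifest, file.path(out_folder, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Generate the toy RDF dataset the fixture queries run on
#'
#' Typed Taxon/Protein/Annotation entities with labels, scientific names
#' (containing the token "species"), organism links and disease annotations,
#' arranged so that every non-defective fixture query returns at least one
#' result.
#'
#' @param n_taxa Number of taxa.
#' @param n_proteins Number of proteins.
#' @param seed Integer seed (controls the protein-to-taxon assignment).
#' @return An [rdf_graph()].
#' @export
generate_toy_dataset <- function(n_taxa = 6L, n_proteins = 10L, seed = 42L) {
  fixture_seed(seed)
  a <- rdf_iri(paste0(RDF_NS, "type"))
  label <- rdf_iri(paste0(RDFS_NS, "label"))
  s <- character(0); p <- character(0); o <- character(0)
  add <- function(ss, pp, oo) { s <<- c(s, ss); p <<- c(p, pp); o <<- c(o, oo) }
  taxa <- if (n_taxa > 0L) rdf_iri(paste0(TOY_TAXON_NS, "T", seq_len(n_taxa))) else character(0)
  for (i in seq_len(n_taxa)) {
    add(taxa[i], a, rdf_iri(paste0(TOY_NS, "Taxon")))
    add(taxa[i], label, rdf_literal(paste0("Taxon ", i)))
    add(taxa[i], rdf_iri(paste0(TOY_NS, "scientificName")),
        rdf_literal(paste0("Testus species", i)))
  }
  for (i in seq_len(n_proteins)) {
    prot <- rdf_iri(paste0(TOY_PROTEIN_NS, "P", i))
    add(prot, a, rdf_iri(paste0(TOY_NS, "Protein")))
    add(prot, label, rdf_literal(paste0("Protein ", i)))
    if (n_taxa > 0L) add(prot, rdf_iri(paste0(TOY_NS, "organism")), taxa[sample.int(n_taxa, 1L)])
    ann <- rdf_iri(paste0(TOY_ANNOT_NS, "A", i))
    add(prot, rdf_iri(paste0(TOY_NS, "annotation")), ann)
    add(ann, a, rdf_iri(paste0(TOY_NS, "Annotation")))
    add(ann, rdf_iri(paste0(TOY_NS, "disease")), rdf_literal(paste0("Disease ", (i %% 3L) + 1L)))
  }
  rdf_graph(s, p, o)
}
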