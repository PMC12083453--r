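# Publishing: per-endpoint merged graphs, the well-known named-graph IRI
# convention, "querying for queries", and the Bio-Query JSON export.

WELL_KNOWN_SUFFIX <- ".well-known/sparql-examples"

#' Named graph IRI for an endpoint's example collection
#'
#' Examples are published in a named graph at the endpoint's address joined
#' with the `.well-known/sparql-examples` suffix.
#'
#' @param endpoint Absolute endpoint IRI.
#' @return The named graph IRI.
#' @export
named_graph_iri <- function(endpoint) {
  if (!is_absolute_iri(endpoint)) stop("endpoint must be an absolute IRI: ", endpoint)
  if (endsWith(endpoint, "/")) paste0(endpoint, WELL_KNOWN_SUFFIX)
  else paste0(endpoint, "/", WELL_KNOWN_SUFFIX)
}

#' Merge the examples targeting one endpoint into a single graph
#'
#' Includes exactly the examples whose targets contain `endpoint`, with any
#' shared prefix declarations materialized per example, as one publishable
#' Turtle document.
#'
#' @param collection An [example_collection()].
#' @param endpoint Endpoint IRI.
#' @return list of class `merged_graph`: `endpoint`, `graph_iri`
#'   (from [named_graph_iri()]), `graph` (an [rdf_graph()]) and `n_examples`.
#' @export
merge_collection <- function(collection, endpoint) {
  giri <- named_graph_iri(endpoint)
  parts <- list()
  n <- 0L
  for (i in seq_along(collection$examples)) {
    doc <- collection$examples[[i]]
    if (!endpoint %in% doc$targets) next
    ttl <- tryCatch(serialize_example(doc), error = function(e) NULL)
    if (is.null(ttl)) {
      warning("skipping unserializable example ", doc$id, " in merge")
      next
    }
    parts[[length(parts) + 1L]] <- parse_rdf(ttl, bnode_prefix = paste0("m", i))
    n <- n + 1L
  }
  if (!n) warning("no examples target endpoint ", endpoint)
  graph <- do.call(rbind_graphs, parts)
  structure(list(endpoint = endpoint, graph_iri = giri, graph = graph, n_examples = n),
            class = "merged_graph")
}

#' @export
print.merged_graph <- function(x, ...) {
  cat("<merged_graph>", x$n_examples, "example(s) for", x$endpoint, "\n")
  cat("  named graph:", x$graph_iri, "\n")
  invisible(x)
}

#' Serialize a merged graph as one Turtle document
#'
#' @param merged A [merge_collection()] result.
#' @param path Optional output file.
#' @return The Turtle text (invisibly when `path` is given).
#' @export
serialize_merged_graph <- function(merged, path = NULL) {
  ttl <- serialize_rdf(merged$graph, prefixes = c(
    sh = SH_NS, rdfs = RDFS_NS, schema = SCHEMA_NS, spex = SPEX_NS, xsd = XSD))
  if (is.null(path)) return(ttl)
  writeLines(ttl, path)
  invisible(ttl)
}

#' Search the merged examples by question keyword ("querying for queries")
#'
#' Runs the canonical retrieval pattern -- `?ex sh:select ?query .
#' ?ex rdfs:comment ?question . FILTER(CONTAINS(?question, <keyword>))` --
#' over the merged graph with the package's own SPARQL engine. Matching is
#' case-sensitive substring containment by default.
#'
#' @param merged A `merged_graph` (or a bare [rdf_graph()]).
#' @param keyword Substring to search for in the questions.
#' @param ignore_case Lowercase both sides before matching.
#' @return data.frame with columns `example`, `question`, `query`.
#' @export
query_for_queries <- function(merged, keyword = "", ignore_case = FALSE) {
  graph <- if (inherits(merged, "merged_graph")) merged$graph else merged
  filter <- if (ignore_case)
    sprintf('FILTER (CONTAINS(LCASE(?question), LCASE("%s")))', escape_string(keyword))
  else
    sprintf('FILTER (CONTAINS(?question, "%s"))', escape_string(keyword))
  qtext <- paste0(
    "PREFIX rdfs: <", RDFS_NS, ">\n",
    "PREFIX sh: <", SH_NS, ">\n",
    "SELECT * WHERE {\n",
    "  ?ex sh:select ?query .\n",
    "  ?ex rdfs:comment ?question .\n  ", filter, "\n}")
  res <- sparql_eval(qtext, graph)
  data.frame(example = iri_value(res$ex %||% character(0)),
             question = if (nrow(res)) literal_value(res$question) else character(0),
             query = if (nrow(res)) literal_value(res$query) else character(0),
             stringsAsFactors = FALSE)
}

#' Export a collection as Bio-Query JSON
#'
#' One record per example: `category` is the resource folder that contributed
#' it, `label` the first English question (falling back to the first
#' question), plus the query text, target endpoints and keywords. Records are
#' ordered by identifier.
#'
#' @param collection An [example_collection()].
#' @param path Optional output file.
#' @return JSON text.
#' @export
export_bioquery_json <- function(collection, path = NULL) {
  records <- lapply(seq_along(collection$examples), function(i) {
    doc <- collection$examples[[i]]
    label <- NA_character_
    if (nrow(doc$comments)) {
      en <- which(!is.na(doc$comments$lang) & startsWith(doc$comments$lang, "en"))
      label <- if (length(en)) doc$comments$text[en[1L]] else doc$comments$text[1L]
    }
    list(id = doc$id, category = collection$resources[i], label = label,
         query = doc$query, target = as.list(unname(doc$targets)), keywords = as.list(unname(doc$keywords)))
  })
  ids <- vapply(records, function(r) r$id %||% "", character(1))
  records <- records[order(ids)]
  json <- jsonlite::toJSON(records, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  json
}
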