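# Query graphs and Mermaid rendering.
#
# A query's basic triple patterns become numbered edges; sequence property
# paths are decomposed through anonymous intermediary nodes (small circles);
# projected variables are styled distinctly; SERVICE bodies are grouped in a
# subgraph naming the remote endpoint. Everything is deterministic: anonymous
# ids come from a counter in pattern order, never from randomness.

DEFAULT_DISPLAY_PREFIXES <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd = "http://www.w3.org/2001/XMLSchema#",
  owl = "http://www.w3.org/2002/07/owl#",
  skos = "http://www.w3.org/2004/02/skos/core#",
  sh = "http://www.w3.org/ns/shacl#",
  schema = "https://schema.org/",
  void = "http://rdfs.org/ns/void#",
  up = "http://purl.uniprot.org/core/")

# Hex-escapes every non-alphanumeric character: total and injective, so two
# distinct terms can never share a node id.
mermaid_id_sanitize <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    if (grepl("^[A-Za-z0-9]$", ch)) ch
    else paste0("_x", paste(sprintf("%02X", utf8ToInt(ch)), collapse = ""))
  }, character(1)), collapse = "")
}

truncate_label <- function(x, n = 30L) {
  if (nchar(x) > n) paste0(substr(x, 1L, n), "…") else x
}

display_term <- function(term, prefixes) {
  tt <- term_type(term)
  if (is.na(tt)) return(term)
  switch(tt,
    var = term,
    iri = {
      if (term == rdf_iri(paste0(RDF_NS, "type"))) return("a")
      cur <- compact_iri(iri_value(term), prefixes)
      if (!is.na(cur)) cur else paste0("<", truncate_label(iri_value(term), 60L), ">")
    },
    literal = truncate_label(literal_parts(term)$value),
    bnode = "[]",
    term)
}

#' Build a labeled graph from a SPARQL query
#'
#' @param query_text Query text or a parsed `sparql_query`.
#' @param prefixes Optional [prefix_map()] used both for parsing prefixed
#'   names and for CURIE display labels (package display defaults are
#'   appended).
#' @return An object of class `query_graph` with `nodes`
#'   (id, role, label), `edges` (ordinal, from, label, to, context) and
#'   `projected` (variable node ids).
#' @export
build_query_graph <- function(query_text, prefixes = NULL) {
  q <- if (inherits(query_text, "sparql_query")) query_text
       else tryCatch(parse_sparql(query_text, extra_prefixes = prefixes %||% character(0)),
                     error = function(e) stop("graph error: ", conditionMessage(e), call. = FALSE))
  disp <- c(prefixes %||% character(0), q$prefixes, DEFAULT_DISPLAY_PREFIXES)
  disp <- disp[!duplicated(names(disp))]

  nodes <- list()   # id -> list(role, label)
  used_ids <- character(0)
  node_for <- function(term) {
    role <- switch(term_type(term), var = "variable", iri = "iri", literal = "literal",
                   bnode = "anonymous", "iri")
    if (startsWith(term, "_anon")) role <- "anonymous"
    id <- paste0(substr(role, 1L, 1L), "_", mermaid_id_sanitize(term))
    if (!id %in% names(nodes)) {
      label <- if (role == "anonymous") "" else display_term(term, disp)
      nodes[[id]] <<- list(role = role, label = label)
    }
    id
  }

  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  edges <- list()
  add_edges <- function(tps, context) {
    for (tp in tps) {
      dec <- decompose_tp_edges(tp$s, tp$p, tp$o, counter)
      for (i in seq_len(nrow(dec))) {
        from <- node_for(dec$s[i])
        to <- node_for(dec$o[i])
        lab <- if (dec$is_expr[i]) dec$label[i] else display_term(dec$label[i], disp)
        edges[[length(edges) + 1L]] <<- data.frame(
          ordinal = length(edges) + 1L, from = from, label = lab, to = to,
          context = context, stringsAsFactors = FALSE)
      }
    }
  }
  walk_ctx <- function(node, context) {
    if (is.null(node)) return(invisible())
    switch(node$type,
      group = for (e in node$elts) walk_ctx(e, context),
      tp = add_edges(list(node), context),
      optional = walk_ctx(node$group, "optional"),
      minus = walk_ctx(node$group, "minus"),
      nested = walk_ctx(node$group, context),
      union = for (b in node$branches) walk_ctx(b, "union"),
      service = walk_ctx(node$group, paste0("service(", iri_value_or_var(node$endpoint), ")")),
      graph = walk_ctx(node$group, context),
      subselect = walk_ctx(node$query$where, "subquery"),
      filter = walk_exists_ctx(node$expr, context),
      bind = walk_exists_ctx(node$expr, context),
      NULL)
    invisible()
  }
  walk_exists_ctx <- function(e, context) {
    if (is.character(e) || !is.list(e)) return(invisible())
    if (identical(e$type, "exists")) walk_ctx(e$group, context)
    for (x in e) if (is.list(x)) {
      if (!is.null(x$type)) walk_exists_ctx(x, context)
      else for (y in x) if (is.list(y)) walk_exists_ctx(y, context)
    }
    invisible()
  }
  walk_ctx(q$where, "base")

  projected_vars <- if (q$form == "select") {
    if (isTRUE(q$star)) pattern_visible_vars(q$where)
    else vapply(q$projection, function(p) p$var, character(1))
  } else character(0)
  projected <- vapply(projected_vars, function(v) paste0("v_", mermaid_id_sanitize(v)), character(1))
  projected <- intersect(unname(projected), names(nodes))

  nodes_df <- if (length(nodes)) data.frame(
    id = names(nodes),
    role = vapply(nodes, `[[`, character(1), "role"),
    label = vapply(nodes, `[[`, character(1), "label"),
    stringsAsFactors = FALSE, row.names = NULL)
  else data.frame(id = character(0), role = character(0), label = character(0),
                  stringsAsFactors = FALSE)
  edges_df <- if (length(edges)) do.call(rbind, edges)
  else data.frame(ordinal = integer(0), from = character(0), label = character(0),
                  to = character(0), context = character(0), stringsAsFactors = FALSE)
  structure(list(nodes = nodes_df, edges = edges_df, projected = projected),
            class = "query_graph")
}

#' @export
print.query_graph <- function(x, ...) {
  cat("<query_graph>", nrow(x$nodes), "node(s),", nrow(x$edges), "edge(s),",
      length(x$projected), "projected\n")
  invisible(x)
}

mermaid_escape <- function(x) {
  x <- gsub('"', "#quot;", x, fixed = TRUE)
  x
}

#' Render a query graph as a Mermaid diagram
#'
#' Projected variables carry the `projected` style class, anonymous path
#' nodes render as small circles, edge labels are prefixed with their
#' ordinal, and SERVICE-context edges sit in a subgraph naming the endpoint.
#' Output is byte-deterministic for identical input.
#'
#' @param graph A [build_query_graph()] result.
#' @param direction Mermaid direction ("TD" or "LR").
#' @return list of class `mermaid_document` with `text` and `direction`.
#' @export
render_mermaid <- function(graph, direction = "TD") {
  lines <- c(paste0("graph ", direction))
  for (i in seq_len(nrow(graph$nodes))) {
    n <- graph$nodes[i, ]
    stmt <- switch(n$role,
      anonymous = paste0("  ", n$id, '(( ))'),
      literal = paste0("  ", n$id, '["', mermaid_escape(n$label), '"]'),
      variable = paste0("  ", n$id, '["', mermaid_escape(n$label), '"]'),
      paste0("  ", n$id, '["', mermaid_escape(n$label), '"]'))
    if (n$id %in% graph$projected) stmt <- paste0(stmt, ":::projected")
    if (n$role == "anonymous") stmt <- paste0(stmt, ":::anon")
    lines <- c(lines, stmt)
  }
  edge_line <- function(e, indent = "  ") {
    tag <- if (e$context %in% c("base") || startsWith(e$context, "service")) ""
           else paste0("(", e$context, ") ")
    lab <- mermaid_escape(paste0(e$ordinal, ". ", tag, e$label))
    dashed <- !e$context %in% "base" && !startsWith(e$context, "service")
    if (dashed) paste0(indent, e$from, ' -. "', lab, '" .-> ', e$to)
    else paste0(indent, e$from, ' -- "', lab, '" --> ', e$to)
  }
  svc_contexts <- unique(graph$edges$context[startsWith(graph$edges$context, "service(")])
  plain <- graph$edges[!startsWith(graph$edges$context, "service("), , drop = FALSE]
  for (i in seq_len(nrow(plain))) lines <- c(lines, edge_line(plain[i, ]))
  for (k in seq_along(svc_contexts)) {
    ctx <- svc_contexts[k]
    endpoint <- sub("^service\\((.*)\\)$", "\\1", ctx)
    lines <- c(lines, paste0("  subgraph service", k, ' ["SERVICE ', mermaid_escape(endpoint), '"]'))
    sub_edges <- graph$edges[graph$edges$context == ctx, , drop = FALSE]
    for (i in seq_len(nrow(sub_edges))) lines <- c(lines, edge_line(sub_edges[i, ], "    "))
    lines <- c(lines, "  end")
  }
  lines <- c(lines,
    "  classDef projected fill:#d5e8d4,stroke:#82b366",
    "  classDef anon fill:#ffffff,stroke:#666666")
  structure(list(text = paste(lines, collapse = "\n"), direction = direction),
            class = "mermaid_document")
}

#' @export
print.mermaid_document <- function(x, ...) { cat(x$text, "\n"); invisible(x) }

iri_value_or_var <- function(x) if (startsWith(x, "?")) x else iri_value(x)

#' Render the Markdown page for one example
#'
#' The page carries the question(s) (with language labels when more than one
#' language is present), keywords, target endpoints, the Mermaid diagram and
#' the query in a fenced code block. If the query does not parse, an error
#' notice replaces the diagram.
#'
#' @param doc An [example_document()].
#' @return Markdown text.
#' @export
render_markdown_page <- function(doc) {
  title <- if (nrow(doc$comments)) doc$comments$text[1L] else doc$id
  lines <- c(paste0("# ", title), "")
  if (nrow(doc$comments) > 1L) {
    for (i in seq_len(nrow(doc$comments))) {
      tag <- if (!is.na(doc$comments$lang[i])) paste0(" (`", doc$comments$lang[i], "`)") else ""
      lines <- c(lines, paste0("- ", doc$comments$text[i], tag))
    }
    lines <- c(lines, "")
  }
  if (length(doc$keywords))
    lines <- c(lines, paste0("**Keywords:** ", paste(doc$keywords, collapse = ", ")), "")
  lines <- c(lines, "**Target endpoint(s):**", paste0("- <", doc$targets, ">"), "")
  if (length(doc$federates_with))
    lines <- c(lines, paste0("**Federates with:** ",
                             paste(paste0("<", doc$federates_with, ">"), collapse = ", ")), "")
  diagram <- tryCatch({
    g <- build_query_graph(doc$query, prefixes = doc$prefixes)
    render_mermaid(g)$text
  }, error = function(e) NULL)
  if (is.null(diagram)) {
    lines <- c(lines, "> Diagram unavailable: the query could not be parsed.", "")
  } else {
    lines <- c(lines, "```mermaid", diagram, "```", "")
  }
  lines <- c(lines, "```sparql", doc$query, "```", "")
  paste(lines, collapse = "\n")
}

#' Render Markdown pages for a whole collection
#'
#' Writes one page per example (mirroring the resource folder layout) plus an
#' `index.md` linking all pages.
#'
#' @param collection An [example_collection()].
#' @param out_dir Output folder.
#' @return Invisibly, the paths written.
#' @export
render_collection_pages <- function(collection, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  index <- c("# SPARQL query examples", "")
  for (res in sort(unique(collection$resources))) {
    idx <- which(collection$resources == res)
    dir.create(file.path(out_dir, res), recursive = TRUE, showWarnings = FALSE)
    index <- c(index, paste0("## ", res), "")
    for (i in idx) {
      doc <- collection$examples[[i]]
      slug <- if (!is.na(doc$id)) basename(sub("/+$", "", doc$id)) else paste0("example-", i)
      rel <- file.path(res, paste0(slug, ".md"))
      path <- file.path(out_dir, rel)
      writeLines(render_markdown_page(doc), path)
      written <- c(written, path)
      q1 <- if (nrow(doc$comments)) doc$comments$text[1L] else slug
      index <- c(index, paste0("- [", q1, "](", rel, ")"))
    }
    index <- c(index, "")
  }
  index_path <- file.path(out_dir, "index.md")
  writeLines(paste(index, collapse = "\n"), index_path)
  invisible(c(written, index_path))
}
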