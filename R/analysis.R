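# Per-query and per-collection complexity metrics.
#
# Triple-pattern counting convention: basic triple patterns are counted in
# every group graph pattern (OPTIONAL, UNION branches, MINUS, GRAPH, SERVICE
# bodies, subqueries and EXISTS bodies). A sequence property path of length k
# counts as k patterns -- the same decomposition the visualizer draws -- while
# non-decomposable path operators (alternation, modifiers, negated sets)
# count as 1. VALUES contributes 0.

# Decomposes one triple pattern into edge rows (shared with the visualizer).
# Returns data.frame(s, label, o, is_expr) where `label` is an encoded term
# (IRI or variable) or, when is_expr, a rendered path expression.
decompose_tp_edges <- function(s, p, o, counter) {
  if (is.character(p)) {
    return(data.frame(s = s, label = p, o = o, is_expr = FALSE, stringsAsFactors = FALSE))
  }
  switch(p$op,
    inv = decompose_tp_edges(o, p$elts[[1L]], s, counter),
    seq = {
      nodes <- s
      for (k in seq_len(length(p$elts) - 1L)) {
        counter$n <- counter$n + 1L
        nodes <- c(nodes, paste0("_anon", counter$n))
      }
      nodes <- c(nodes, o)
      parts <- lapply(seq_along(p$elts), function(k)
        decompose_tp_edges(nodes[k], p$elts[[k]], nodes[k + 1L], counter))
      do.call(rbind, parts)
    },
    # alternation, cardinality modifiers and negated sets stay one edge
    data.frame(s = s, label = serialize_path(p), o = o, is_expr = TRUE, stringsAsFactors = FALSE))
}

tp_pattern_count <- function(tp) {
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  nrow(decompose_tp_edges(tp$s, tp$p, tp$o, counter))
}

walk_pattern <- function(node, visit) {
  if (is.null(node)) return(invisible())
  visit(node)
  kids <- switch(node$type,
    group = node$elts,
    optional = , minus = , nested = , service = , graph = list(node$group),
    union = node$branches,
    subselect = list(node$query$where),
    list())
  for (k in kids) walk_pattern(k, visit)
  if (identical(node$type, "filter")) walk_expr_groups(node$expr, visit)
  if (identical(node$type, "bind")) walk_expr_groups(node$expr, visit)
  if (identical(node$type, "subselect")) {
    for (p in node$query$projection) if (!is.null(p$expr)) walk_expr_groups(p$expr, visit)
    for (h in node$query$having %||% list()) walk_expr_groups(h, visit)
  }
  invisible()
}

walk_expr_groups <- function(e, visit) {
  if (is.character(e) || !is.list(e)) return(invisible())
  if (identical(e$type, "exists")) walk_pattern(e$group, visit)
  for (x in e) if (is.list(x)) {
    if (!is.null(x$type) && x$type %in% c("op", "call", "in", "exists")) walk_expr_groups(x, visit)
    else if (is.null(x$type)) for (y in x) if (is.list(y)) walk_expr_groups(y, visit)
  }
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

count_aggregates_in_expr <- function(e, acc) {
  if (is.character(e) || !is.list(e)) return(invisible())
  if (identical(e$type, "call") && isTRUE(e$aggregate))
    acc[[e$name]] <- (acc[[e$name]] %||% 0L) + 1L
  for (x in e) if (is.list(x)) {
    if (!is.null(x$type)) count_aggregates_in_expr(x, acc)
    else for (y in x) if (is.list(y)) count_aggregates_in_expr(y, acc)
  }
  invisible()
}

query_exprs <- function(q) {
  out <- list()
  for (p in q$projection %||% list()) if (!is.null(p$expr)) out <- c(out, list(p$expr))
  for (h in q$having %||% list()) out <- c(out, list(h))
  for (o in q$order_by %||% list()) out <- c(out, list(o$expr))
  for (g in q$group_by %||% list()) if (is.list(g) && !is.null(g$expr)) out <- c(out, list(g$expr))
  out
}

# All variables visible at the top level of a pattern (for SELECT *).
pattern_visible_vars <- function(node) {
  vars <- character(0)
  grab <- function(x) if (is.character(x) && length(x) == 1L && startsWith(x, "?")) vars <<- c(vars, x)
  rec <- function(n) {
    if (is.null(n)) return()
    switch(n$type,
      group = for (e in n$elts) rec(e),
      tp = { grab(n$s); grab(n$p); grab(n$o) },
      optional = , nested = , service = , graph = rec(n$group),
      union = for (b in n$branches) rec(b),
      bind = grab(n$var),
      values = for (v in n$vars) grab(v),
      subselect = {
        if (isTRUE(n$query$star)) rec(n$query$where)
        else for (p in n$query$projection) grab(p$var)
      },
      minus = NULL,   # MINUS does not bind outside
      NULL)
  }
  rec(node)
  unique(vars)
}

#' Analyze the complexity of a SPARQL query
#'
#' @param query_text Query text, or a parsed `sparql_query`.
#' @param prefixes Optional [prefix_map()] (or named character vector) made
#'   available in addition to the query's own PREFIX declarations.
#' @return An object of class `query_metrics`: `triple_pattern_count`,
#'   `aggregate_counts` (named integer vector over SUM/COUNT/AVG/MIN/MAX/
#'   GROUP_CONCAT/SAMPLE), `service_endpoints` (IRIs, or "variable" for a
#'   variable endpoint), feature flags (`uses_optional`, `uses_union`,
#'   `uses_subquery`, `uses_property_path`, `uses_filter`), `federated`, and
#'   `projected_variables`.
#' @export
analyze_query <- function(query_text, prefixes = NULL) {
  q <- if (inherits(query_text, "sparql_query")) query_text
       else tryCatch(parse_sparql(query_text, extra_prefixes = prefixes %||% character(0)),
                     error = function(e) stop("analysis error: ", conditionMessage(e), call. = FALSE))
  tp_count <- 0L
  agg <- new.env(parent = emptyenv())
  services <- character(0)
  flags <- c(optional = FALSE, union = FALSE, subquery = FALSE, path = FALSE, filter = FALSE)
  visit <- function(node) {
    switch(node$type,
      tp = {
        tp_count <<- tp_count + tp_pattern_count(node)
        if (!is.character(node$p)) flags["path"] <<- TRUE
      },
      optional = flags["optional"] <<- TRUE,
      union = flags["union"] <<- TRUE,
      subselect = {
        flags["subquery"] <<- TRUE
        for (e in query_exprs(node$query)) count_aggregates_in_expr(e, agg)
      },
      filter = { flags["filter"] <<- TRUE; count_aggregates_in_expr(node$expr, agg) },
      bind = count_aggregates_in_expr(node$expr, agg),
      service = services <<- c(services,
        if (startsWith(node$endpoint, "?")) "variable" else iri_value(node$endpoint)),
      NULL)
  }
  walk_pattern(q$where, visit)
  for (e in query_exprs(q)) count_aggregates_in_expr(e, agg)

  agg_counts <- stats::setNames(integer(length(SPARQL_AGGREGATES)), SPARQL_AGGREGATES)
  for (nm in ls(agg)) agg_counts[[nm]] <- agg[[nm]]

  projected <- if (q$form == "select") {
    if (isTRUE(q$star)) pattern_visible_vars(q$where)
    else vapply(q$projection, function(p) p$var, character(1))
  } else character(0)

  structure(list(
    form = q$form,
    triple_pattern_count = tp_count,
    aggregate_counts = agg_counts,
    service_endpoints = unique(services),
    federated = length(services) > 0L,
    uses_optional = unname(flags["optional"]),
    uses_union = unname(flags["union"]),
    uses_subquery = unname(flags["subquery"]),
    uses_property_path = unname(flags["path"]),
    uses_filter = unname(flags["filter"]),
    projected_variables = projected), class = "query_metrics")
}

#' @export
print.query_metrics <- function(x, ...) {
  cat("<query_metrics>", x$form, "query:", x$triple_pattern_count, "triple pattern(s),",
      sum(x$aggregate_counts), "aggregation(s)",
      if (x$federated) paste0("; federated (", paste(x$service_endpoints, collapse = ", "), ")"), "\n")
  invisible(x)
}

#' Per-endpoint complexity statistics for a collection
#'
#' One row per distinct target endpoint; an example with several targets
#' contributes to each of its endpoints' rows. Means are computed exactly and
#' only rounded for display.
#'
#' @param collection An [example_collection()].
#' @return A data.frame of class `collection_stats` with columns `endpoint`,
#'   `n_queries`, `n_federated`, `mean_triple_patterns`, `total_aggregations`.
#'   Unanalyzable examples are excluded and listed in the `excluded`
#'   attribute.
#' @export
collection_stats <- function(collection) {
  rows <- list()
  excluded <- data.frame(id = character(0), message = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(collection$examples)) {
    doc <- collection$examples[[i]]
    m <- tryCatch(analyze_query(doc$query, prefixes = doc$prefixes), error = function(e) e)
    if (inherits(m, "error")) {
      excluded <- rbind(excluded, data.frame(id = doc$id, message = conditionMessage(m),
                                             stringsAsFactors = FALSE))
      next
    }
    for (ep in doc$targets)
      rows[[length(rows) + 1L]] <- data.frame(endpoint = ep, tp = m$triple_pattern_count,
                                              fed = m$federated, agg = sum(m$aggregate_counts),
                                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(endpoint = character(0), n_queries = integer(0), n_federated = integer(0),
                      mean_triple_patterns = numeric(0), total_aggregations = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    all <- do.call(rbind, rows)
    eps <- sort(unique(all$endpoint))
    out <- do.call(rbind, lapply(eps, function(ep) {
      sub <- all[all$endpoint == ep, , drop = FALSE]
      data.frame(endpoint = ep, n_queries = nrow(sub), n_federated = sum(sub$fed),
                 mean_triple_patterns = sum(sub$tp) / nrow(sub),
                 total_aggregations = sum(sub$agg), stringsAsFactors = FALSE)
    }))
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("collection_stats", "data.frame")
  out
}

#' @export
print.collection_stats <- function(x, ...) {
  df <- as.data.frame(x)
  df$mean_triple_patterns <- round(df$mean_triple_patterns, 1L)  # display rounding only
  print(df)
  invisible(x)
}

#' Write collection statistics as TSV or JSON
#'
#' @param stats A `collection_stats` data.frame.
#' @param path Output file.
#' @param format "tsv" or "json".
#' @export
write_collection_stats <- function(stats, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(stats)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
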