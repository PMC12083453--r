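# In-memory SPARQL evaluation over an rdf_graph.
#
# Solution sequences are data.frames whose columns are variable names (no "?")
# holding encoded RDF terms; NA marks an unbound variable. Evaluation is
# multiset-preserving except where SPARQL itself deduplicates (DISTINCT).
#
# Local evaluation is deliberately self-contained: FROM dataset clauses are
# informational (the supplied graph *is* the dataset) and SERVICE bodies are
# evaluated against the local graph, so probing never touches the network.

var_name <- function(v) sub("^[?$]", "", v)

# A single solution row with no columns: data.frame with one row, zero cols.
one_row_df <- function() {
  df <- data.frame(x = 1L)
  df$x <- NULL
  df
}

sol_join <- function(a, b) {
  if (is.null(a)) return(b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    cols <- union(names(a), names(b))
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  shared <- intersect(names(a), names(b))
  if (!length(shared)) {
    idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    out <- cbind(a[idx$i, , drop = FALSE], b[idx$j, , drop = FALSE])
    rownames(out) <- NULL
    return(out)
  }
  out <- merge(a, b, by = shared, incomparables = NULL)
  rownames(out) <- NULL
  out
}

sol_left_join <- function(a, b) {
  if (nrow(a) == 0L) {
    cols <- union(names(a), names(b))
    return(as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE))
  }
  a$.row_id <- seq_len(nrow(a))
  joined <- sol_join(a, b)
  missing_rows <- setdiff(a$.row_id, joined$.row_id)
  if (length(missing_rows)) {
    extra <- a[a$.row_id %in% missing_rows, , drop = FALSE]
    for (col in setdiff(names(joined), names(extra))) extra[[col]] <- NA_character_
    joined <- rbind(joined[, names(joined), drop = FALSE], extra[, names(joined), drop = FALSE])
  }
  joined$.row_id <- NULL
  a$.row_id <- NULL
  rownames(joined) <- NULL
  joined
}

sol_union <- function(a, b) {
  cols <- union(names(a), names(b))
  for (col in setdiff(cols, names(a))) a[[col]] <- rep(NA_character_, nrow(a))
  for (col in setdiff(cols, names(b))) b[[col]] <- rep(NA_character_, nrow(b))
  out <- rbind(a[, cols, drop = FALSE], b[, cols, drop = FALSE])
  rownames(out) <- NULL
  out
}

sol_minus <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) return(a)
  keep <- vapply(seq_len(nrow(a)), function(i) {
    arow <- a[i, shared, drop = FALSE]
    for (j in seq_len(nrow(b))) {
      brow <- b[j, shared, drop = FALSE]
      both <- !is.na(unlist(arow)) & !is.na(unlist(brow))
      if (!any(both)) next   # disjoint domains: not compatible for MINUS
      if (all(unlist(arow)[both] == unlist(brow)[both])) return(FALSE)
    }
    TRUE
  }, logical(1))
  a[keep, , drop = FALSE]
}

## --------------------------------------------------------------------------
## triple pattern and path matching

# Returns a binding table for a triple pattern with a simple predicate.
match_simple_tp <- function(graph, s, p, o) {
  rows <- graph
  sel <- rep(TRUE, nrow(rows))
  if (!startsWith(s, "?")) sel <- sel & rows$s == s
  if (!startsWith(p, "?")) sel <- sel & rows$p == p
  if (!startsWith(o, "?")) sel <- sel & rows$o == o
  rows <- rows[sel, , drop = FALSE]
  out <- list()
  if (startsWith(s, "?")) out[[var_name(s)]] <- rows$s
  if (startsWith(p, "?")) out[[var_name(p)]] <- rows$p
  if (startsWith(o, "?")) out[[var_name(o)]] <- rows$o
  if (!length(out)) {
    df <- one_row_df()
    return(if (nrow(rows) > 0L) df else df[0L, , drop = FALSE])
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  # same variable used twice in one pattern: keep rows where occurrences agree
  dup_pairs <- list(c(s, o), c(s, p), c(p, o))
  vals <- list(c("s", "o"), c("s", "p"), c("p", "o"))
  for (k in seq_along(dup_pairs)) {
    pr <- dup_pairs[[k]]
    if (startsWith(pr[1], "?") && startsWith(pr[2], "?") && pr[1] == pr[2]) {
      df <- df[rows[[vals[[k]][1]]] == rows[[vals[[k]][2]]], , drop = FALSE]
      rows <- rows[rows[[vals[[k]][1]]] == rows[[vals[[k]][2]]], , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df
}

# Pair table (from, to) for one path step.
path_pairs <- function(graph, path) {
  if (is.character(path)) {
    rows <- graph[graph$p == path, , drop = FALSE]
    return(data.frame(from = rows$s, to = rows$o, stringsAsFactors = FALSE))
  }
  switch(path$op,
    inv = { p <- path_pairs(graph, path$elts[[1L]]); data.frame(from = p$to, to = p$from, stringsAsFactors = FALSE) },
    alt = {
      parts <- lapply(path$elts, path_pairs, graph = graph)
      do.call(rbind, parts)
    },
    seq = {
      acc <- path_pairs(graph, path$elts[[1L]])
      for (elt in path$elts[-1L]) {
        nxt <- path_pairs(graph, elt)
        acc <- merge(acc, nxt, by.x = "to", by.y = "from")[, c("from", "to.y")]
        names(acc) <- c("from", "to")
      }
      acc
    },
    mod = {
      base <- unique(path_pairs(graph, path$elts[[1L]]))
      nodes <- unique(c(graph$s, graph$o))
      closure <- base
      repeat {
        step <- merge(closure, base, by.x = "to", by.y = "from")[, c("from", "to.y")]
        names(step) <- c("from", "to")
        new <- unique(rbind(closure, step))
        if (nrow(new) == nrow(closure)) break
        closure <- new
      }
      ident <- data.frame(from = nodes, to = nodes, stringsAsFactors = FALSE)
      switch(path$mod,
        "+" = closure,
        "*" = unique(rbind(ident, closure)),
        "?" = unique(rbind(ident, base)))
    },
    neg = {
      excluded <- negated_iris(path$elts[[1L]])
      rows <- graph[!graph$p %in% excluded, , drop = FALSE]
      data.frame(from = rows$s, to = rows$o, stringsAsFactors = FALSE)
    },
    stop("unsupported path operator in local evaluation: ", path$op))
}

negated_iris <- function(p) {
  if (is.character(p)) return(p)
  if (p$op == "alt") return(unlist(lapply(p$elts, negated_iris)))
  stop("unsupported negated property set in local evaluation")
}

match_tp <- function(graph, tp) {
  if (is.character(tp$p)) return(match_simple_tp(graph, tp$s, tp$p, tp$o))
  pairs <- path_pairs(graph, tp$p)
  if (!startsWith(tp$s, "?")) pairs <- pairs[pairs$from == tp$s, , drop = FALSE]
  if (!startsWith(tp$o, "?")) pairs <- pairs[pairs$to == tp$o, , drop = FALSE]
  out <- list()
  if (startsWith(tp$s, "?")) out[[var_name(tp$s)]] <- pairs$from
  if (startsWith(tp$o, "?")) out[[var_name(tp$o)]] <- pairs$to
  if (!length(out)) {
    df <- one_row_df()
    return(if (nrow(pairs) > 0L) df else df[0L, , drop = FALSE])
  }
  if (startsWith(tp$s, "?") && startsWith(tp$o, "?") && tp$s == tp$o) {
    keep <- pairs$from == pairs$to
    out <- lapply(out, function(col) col[keep])
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- NULL
  df
}

## --------------------------------------------------------------------------
## pattern evaluation

eval_group <- function(group, graph, full_graph = graph) {
  sols <- NULL
  for (e in group$elts) {
    sols <- eval_element(e, sols, graph, full_graph)
  }
  if (is.null(sols)) one_row_df() else sols
}

eval_element <- function(e, sols, graph, full_graph) {
  base <- if (is.null(sols)) one_row_df() else sols
  switch(e$type,
    tp = {
      tbl <- match_tp(graph, e)
      if (is.null(sols)) tbl else sol_join(sols, tbl)
    },
    filter = {
      if (!nrow(base)) return(base)
      keep <- vapply(seq_len(nrow(base)), function(i)
        isTRUE(ebv(eval_expr(e$expr, base[i, , drop = FALSE], graph, full_graph))), logical(1))
      base[keep, , drop = FALSE]
    },
    bind = {
      vname <- var_name(e$var)
      if (!nrow(base)) { base[[vname]] <- character(0); return(base) }
      base[[vname]] <- vapply(seq_len(nrow(base)), function(i) {
        v <- eval_expr(e$expr, base[i, , drop = FALSE], graph, full_graph)
        if (is.null(v)) NA_character_ else v
      }, character(1))
      base
    },
    optional = {
      right <- eval_group(e$group, graph, full_graph)
      sol_left_join(base, right)
    },
    minus = sol_minus(base, eval_group(e$group, graph, full_graph)),
    nested = {
      inner <- eval_group(e$group, graph, full_graph)
      if (is.null(sols)) inner else sol_join(sols, inner)
    },
    union = {
      parts <- lapply(e$branches, eval_group, graph = graph, full_graph = full_graph)
      acc <- Reduce(sol_union, parts)
      if (is.null(sols)) acc else sol_join(sols, acc)
    },
    service = {
      inner <- eval_group(e$group, graph, full_graph)
      if (is.null(sols)) inner else sol_join(sols, inner)
    },
    graph = {
      if (startsWith_any(e$name, "?")) {
        gnames <- unique(full_graph$g[!is.na(full_graph$g)])
        acc <- NULL
        for (gn in gnames) {
          part <- eval_group(e$group, graph_slice(full_graph, gn), full_graph)
          part[[var_name(e$name)]] <- rep(rdf_iri(gn), nrow(part))
          acc <- if (is.null(acc)) part else sol_union(acc, part)
        }
        if (is.null(acc)) acc <- one_row_df()[0L, , drop = FALSE]
        if (is.null(sols)) acc else sol_join(sols, acc)
      } else {
        slice <- graph_slice(full_graph, iri_value(e$name))
        inner <- eval_group(e$group, slice, full_graph)
        if (is.null(sols)) inner else sol_join(sols, inner)
      }
    },
    subselect = {
      inner <- eval_query_pattern(e$query, graph, full_graph)
      if (is.null(sols)) inner else sol_join(sols, inner)
    },
    values = {
      tbl <- values_table(e)
      if (is.null(sols)) tbl else sol_join(sols, tbl)
    },
    stop("unknown pattern element: ", e$type))
}

startsWith_any <- function(x, prefix) is.character(x) && length(x) == 1L && startsWith(x, prefix)

values_table <- function(v) {
  cols <- lapply(v$vars, function(vn) vapply(v$rows, function(r) r[[vn]], character(1)))
  df <- as.data.frame(stats::setNames(cols, vapply(v$vars, var_name, character(1))),
                      stringsAsFactors = FALSE, check.names = FALSE)
  df
}

## --------------------------------------------------------------------------
## expressions

numeric_datatypes <- paste0(XSD, c("integer", "decimal", "double", "float", "int", "long", "short", "nonNegativeInteger"))

term_numeric <- function(term) {
  if (is.na(term) || term_type(term) != "literal") return(NA_real_)
  p <- literal_parts(term)
  if (!is.na(p$datatype) && !p$datatype %in% numeric_datatypes) return(NA_real_)
  suppressWarnings(as.numeric(p$value))
}

term_string <- function(term) {
  if (is.na(term)) return(NA_character_)
  switch(term_type(term),
    literal = literal_parts(term)$value,
    iri = iri_value(term),
    term)
}

make_boolean <- function(x) paste0('"', tolower(as.character(x)), '"^^<', XSD, "boolean>")

ebv <- function(term) {
  if (is.null(term) || length(term) != 1L || is.na(term)) return(NA)
  if (is.logical(term)) return(term)
  if (term_type(term) != "literal") return(NA)
  p <- literal_parts(term)
  if (!is.na(p$datatype) && p$datatype == paste0(XSD, "boolean")) return(p$value == "true")
  num <- term_numeric(term)
  if (!is.na(num)) return(num != 0)
  nzchar(p$value)
}

eval_expr <- function(expr, row, graph, full_graph, group_df = NULL) {
  if (is.character(expr)) {
    if (startsWith(expr, "?")) {
      vn <- var_name(expr)
      if (!vn %in% names(row)) return(NA_character_)
      return(row[[vn]][1L])
    }
    return(expr)
  }
  switch(expr$type,
    op = eval_op(expr, row, graph, full_graph, group_df),
    call = {
      if (isTRUE(expr$aggregate)) {
        if (is.null(group_df)) stop("aggregate used outside a grouping context")
        return(eval_aggregate(expr, group_df, graph, full_graph))
      }
      eval_builtin(expr, row, graph, full_graph, group_df)
    },
    "in" = {
      lhs <- eval_expr(expr$lhs, row, graph, full_graph, group_df)
      vals <- vapply(expr$items, eval_expr, character(1), row = row, graph = graph,
                     full_graph = full_graph, group_df = group_df)
      hit <- !is.na(lhs) && lhs %in% vals
      make_boolean(if (expr$negated) !hit else hit)
    },
    exists = {
      inner <- eval_group(expr$group, graph, full_graph)
      bound <- row[, !is.na(unlist(row)), drop = FALSE]
      hit <- nrow(sol_join(bound, inner)) > 0L
      make_boolean(if (expr$negated) !hit else hit)
    },
    stop("unknown expression node: ", expr$type))
}

eval_op <- function(expr, row, graph, full_graph, group_df) {
  op <- expr$op
  a1 <- eval_expr(expr$args[[1L]], row, graph, full_graph, group_df)
  if (op == "!") return(make_boolean(!isTRUE(ebv(a1))))
  if (op == "uminus") return(num_literal(-term_numeric(a1)))
  a2 <- eval_expr(expr$args[[2L]], row, graph, full_graph, group_df)
  if (op == "||") return(make_boolean(isTRUE(ebv(a1)) || isTRUE(ebv(a2))))
  if (op == "&&") return(make_boolean(isTRUE(ebv(a1)) && isTRUE(ebv(a2))))
  if (op %in% c("+", "-", "*", "/")) {
    n1 <- term_numeric(a1); n2 <- term_numeric(a2)
    if (is.na(n1) || is.na(n2)) return(NA_character_)
    return(num_literal(switch(op, "+" = n1 + n2, "-" = n1 - n2, "*" = n1 * n2, "/" = n1 / n2)))
  }
  if (is.na(a1) || is.na(a2)) return(NA_character_)
  n1 <- term_numeric(a1); n2 <- term_numeric(a2)
  res <- if (!is.na(n1) && !is.na(n2)) switch(op,
    "=" = n1 == n2, "!=" = n1 != n2, "<" = n1 < n2, ">" = n1 > n2, "<=" = n1 <= n2, ">=" = n1 >= n2)
  else {
    s1 <- term_string(a1); s2 <- term_string(a2)
    switch(op, "=" = a1 == a2, "!=" = a1 != a2, "<" = s1 < s2, ">" = s1 > s2, "<=" = s1 <= s2, ">=" = s1 >= s2)
  }
  make_boolean(res)
}

num_literal <- function(x) {
  if (is.na(x)) return(NA_character_)
  if (x == floor(x) && abs(x) < 2^53) paste0('"', format(x, scientific = FALSE), '"^^<', XSD, "integer>")
  else paste0('"', format(x, scientific = FALSE), '"^^<', XSD, "decimal>")
}

eval_builtin <- function(expr, row, graph, full_graph, group_df) {
  name <- expr$name
  ev <- function(i) eval_expr(expr$args[[i]], row, graph, full_graph, group_df)
  switch(name,
    BOUND = {
      v <- expr$args[[1L]]
      make_boolean(startsWith(v, "?") && var_name(v) %in% names(row) && !is.na(row[[var_name(v)]][1L]))
    },
    STR = { t <- ev(1L); if (is.na(t)) NA_character_ else rdf_literal(term_string(t)) },
    LANG = { t <- ev(1L); if (is.na(t) || term_type(t) != "literal") NA_character_ else {
      lg <- literal_parts(t)$lang; rdf_literal(if (is.na(lg)) "" else lg) } },
    LANGMATCHES = {
      lg <- term_string(ev(1L)); pat <- term_string(ev(2L))
      make_boolean(!is.na(lg) && nzchar(lg) && (pat == "*" || tolower(lg) == tolower(pat) ||
        startsWith(tolower(lg), paste0(tolower(pat), "-"))))
    },
    DATATYPE = { t <- ev(1L); if (is.na(t) || term_type(t) != "literal") NA_character_
                 else rdf_iri(literal_datatype(t)) },
    CONTAINS = make_boolean(grepl(term_string(ev(2L)), term_string(ev(1L)), fixed = TRUE)),
    STRSTARTS = make_boolean(startsWith(term_string(ev(1L)), term_string(ev(2L)))),
    STRENDS = make_boolean(endsWith(term_string(ev(1L)), term_string(ev(2L)))),
    STRLEN = num_literal(nchar(term_string(ev(1L)))),
    UCASE = rdf_literal(toupper(term_string(ev(1L)))),
    LCASE = rdf_literal(tolower(term_string(ev(1L)))),
    SUBSTR = {
      s <- term_string(ev(1L)); from <- term_numeric(ev(2L))
      len <- if (length(expr$args) > 2L) term_numeric(ev(3L)) else NA_real_
      rdf_literal(if (is.na(len)) substr(s, from, nchar(s)) else substr(s, from, from + len - 1L))
    },
    CONCAT = rdf_literal(paste0(vapply(seq_along(expr$args), function(i) term_string(ev(i)), character(1)), collapse = "")),
    REGEX = {
      flags <- if (length(expr$args) > 2L) term_string(ev(3L)) else ""
      make_boolean(grepl(term_string(ev(2L)), term_string(ev(1L)),
                         ignore.case = grepl("i", flags, fixed = TRUE), perl = TRUE))
    },
    REPLACE = rdf_literal(gsub(term_string(ev(2L)), term_string(ev(3L)), term_string(ev(1L)), perl = TRUE)),
    ABS = num_literal(abs(term_numeric(ev(1L)))),
    CEIL = num_literal(ceiling(term_numeric(ev(1L)))),
    FLOOR = num_literal(floor(term_numeric(ev(1L)))),
    ROUND = num_literal(round(term_numeric(ev(1L)))),
    IF = if (isTRUE(ebv(ev(1L)))) ev(2L) else ev(3L),
    COALESCE = {
      for (i in seq_along(expr$args)) { v <- ev(i); if (!is.na(v)) return(v) }
      NA_character_
    },
    ISIRI = , ISURI = { t <- ev(1L); make_boolean(!is.na(t) && term_type(t) == "iri") },
    ISLITERAL = { t <- ev(1L); make_boolean(!is.na(t) && term_type(t) == "literal") },
    ISBLANK = { t <- ev(1L); make_boolean(!is.na(t) && term_type(t) == "bnode") },
    ISNUMERIC = make_boolean(!is.na(term_numeric(ev(1L)))),
    SAMETERM = make_boolean(identical(ev(1L), ev(2L))),
    IRI = , URI = rdf_iri(term_string(ev(1L))),
    STRLANG = rdf_literal(term_string(ev(1L)), lang = term_string(ev(2L))),
    STRDT = rdf_literal(term_string(ev(1L)), datatype = term_string(ev(2L))),
    stop("unsupported function in local evaluation: ", name))
}

eval_aggregate <- function(call, group_df, graph, full_graph) {
  vals <- if (length(call$args) && identical(call$args[[1L]], "*")) {
    rep("*", nrow(group_df))
  } else {
    arg <- call$args[[1L]]
    vapply(seq_len(max(nrow(group_df), 0L)), function(i)
      eval_expr(arg, group_df[i, , drop = FALSE], graph, full_graph), character(1))
  }
  if (!identical(vals, character(0)) && !identical(vals[1], "*")) vals <- vals[!is.na(vals)]
  if (isTRUE(call$distinct)) vals <- unique(vals)
  switch(call$name,
    COUNT = num_literal(length(vals)),
    SUM = num_literal(sum(vapply(vals, term_numeric, numeric(1)), na.rm = TRUE)),
    AVG = num_literal(if (!length(vals)) 0 else mean(vapply(vals, term_numeric, numeric(1)), na.rm = TRUE)),
    MIN = if (!length(vals)) NA_character_ else vals[order(vapply(vals, sort_key, character(1)))][1L],
    MAX = if (!length(vals)) NA_character_ else vals[order(vapply(vals, sort_key, character(1)), decreasing = TRUE)][1L],
    SAMPLE = if (!length(vals)) NA_character_ else vals[[1L]],
    GROUP_CONCAT = rdf_literal(paste(vapply(vals, term_string, character(1)),
                                     collapse = if (is.null(call$separator)) " " else call$separator)),
    stop("unsupported aggregate: ", call$name))
}

sort_key <- function(term) {
  if (is.na(term)) return("")
  n <- term_numeric(term)
  if (!is.na(n)) return(sprintf("%030.6f", n + 1e12))
  term_string(term)
}

## --------------------------------------------------------------------------
## query forms

expr_has_aggregate <- function(e) {
  if (is.character(e)) return(FALSE)
  if (!is.list(e)) return(FALSE)
  if (identical(e$type, "call") && isTRUE(e$aggregate)) return(TRUE)
  any(vapply(e, function(x) is.list(x) && expr_has_aggregate(x), logical(1)))
}

eval_query_pattern <- function(q, graph, full_graph = graph) {
  df <- eval_group(q$where, graph, full_graph)
  if (!is.null(q$values)) df <- sol_join(df, values_table(q$values))

  uses_aggregates <- !is.null(q$group_by) ||
    any(vapply(q$projection, function(p) !is.null(p$expr) && expr_has_aggregate(p$expr), logical(1))) ||
    (!is.null(q$having) && any(vapply(q$having, expr_has_aggregate, logical(1))))

  if (q$form == "select" && uses_aggregates) {
    df <- eval_grouped(q, df, graph, full_graph)
  } else if (q$form == "select") {
    if (!isTRUE(q$star)) {
      for (p in q$projection) {
        if (!is.null(p$expr)) {
          vn <- var_name(p$var)
          df[[vn]] <- if (nrow(df)) vapply(seq_len(nrow(df)), function(i) {
            v <- eval_expr(p$expr, df[i, , drop = FALSE], graph, full_graph)
            if (is.null(v)) NA_character_ else v
          }, character(1)) else character(0)
        }
      }
      keep <- vapply(q$projection, function(p) var_name(p$var), character(1))
      for (k in setdiff(keep, names(df))) df[[k]] <- rep(NA_character_, nrow(df))
      df <- df[, keep, drop = FALSE]
    }
  }
  if (isTRUE(q$distinct) || isTRUE(q$reduced)) df <- unique(df)
  if (!is.null(q$order_by) && nrow(df)) {
    ord <- do.call(order, lapply(seq_along(q$order_by), function(k) {
      o <- q$order_by[[k]]
      vals <- vapply(seq_len(nrow(df)), function(i) {
        v <- eval_expr(o$expr, df[i, , drop = FALSE], graph, full_graph)
        if (is.null(v) || is.na(v)) "" else sort_key(v)
      }, character(1))
      if (o$dir == "DESC") return(xtfrm(factor(vals, levels = rev(sort(unique(vals))))))
      xtfrm(factor(vals, levels = sort(unique(vals))))
    }))
    df <- df[ord, , drop = FALSE]
  }
  off <- if (!is.null(q$offset) && !is.na(q$offset)) q$offset else 0L
  if (off > 0L) df <- if (off >= nrow(df)) df[0L, , drop = FALSE] else df[(off + 1L):nrow(df), , drop = FALSE]
  if (!is.null(q$limit) && !is.na(q$limit)) df <- utils::head(df, q$limit)
  rownames(df) <- NULL
  df
}

eval_grouped <- function(q, df, graph, full_graph) {
  gb <- q$group_by
  key_cols <- character(0)
  if (!is.null(gb)) {
    for (k in seq_along(gb)) {
      g <- gb[[k]]
      if (is.character(g)) key_cols <- c(key_cols, var_name(g))
      else {
        vn <- if (!is.null(g$var)) var_name(g$var) else paste0(".gkey", k)
        df[[vn]] <- if (nrow(df)) vapply(seq_len(nrow(df)), function(i)
          eval_expr(g$expr, df[i, , drop = FALSE], graph, full_graph), character(1)) else character(0)
        key_cols <- c(key_cols, vn)
      }
    }
  }
  groups <- if (length(key_cols) && nrow(df)) {
    split(seq_len(nrow(df)), interaction(df[, key_cols, drop = FALSE], drop = TRUE, lex.order = TRUE))
  } else list(all = seq_len(nrow(df)))
  if (!length(key_cols) && nrow(df) == 0L) groups <- list(all = integer(0))

  out_rows <- list()
  for (idx in groups) {
    gdf <- df[idx, , drop = FALSE]
    rep_row <- if (nrow(gdf)) gdf[1L, , drop = FALSE] else df[0L, , drop = FALSE][NA_integer_, , drop = FALSE]
    if (!is.null(q$having)) {
      ok <- all(vapply(q$having, function(h)
        isTRUE(ebv(eval_expr(h, rep_row, graph, full_graph, group_df = gdf))), logical(1)))
      if (!ok) next
    }
    row <- list()
    for (p in q$projection) {
      vn <- var_name(p$var)
      row[[vn]] <- if (!is.null(p$expr))
        eval_expr(p$expr, rep_row, graph, full_graph, group_df = gdf)
      else if (vn %in% names(gdf) && nrow(gdf)) gdf[[vn]][1L]
      else NA_character_
      if (is.null(row[[vn]])) row[[vn]] <- NA_character_
    }
    out_rows[[length(out_rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (!length(out_rows)) {
    cols <- vapply(q$projection, function(p) var_name(p$var), character(1))
    return(as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE, check.names = FALSE))
  }
  out <- do.call(rbind, out_rows)
  rownames(out) <- NULL
  out
}

#' Evaluate a SPARQL query against a local graph
#'
#' @param query A `sparql_query` from [parse_sparql()], or query text.
#' @param graph An [rdf_graph()]. Named graphs in the data are visible through
#'   GRAPH patterns; the default evaluation scope is the whole store.
#' @return SELECT: a data.frame of solutions (columns named after the
#'   variables, encoded terms, NA = unbound). ASK: a logical. CONSTRUCT and
#'   DESCRIBE: an [rdf_graph()].
#' @export
sparql_eval <- function(query, graph) {
  q <- if (is.character(query)) parse_sparql(query) else query
  if (q$form == "update") stop("refusing to execute an UPDATE operation")
  if (q$form == "select") return(eval_query_pattern(q, graph))
  if (q$form == "ask") {
    df <- eval_group(q$where, graph, graph)
    if (!is.null(q$values)) df <- sol_join(df, values_table(q$values))
    return(nrow(df) > 0L)
  }
  if (q$form == "construct") {
    df <- eval_query_pattern(c(q[setdiff(names(q), c("form"))], list(form = "select", star = TRUE)), graph)
    s <- character(0); p <- character(0); o <- character(0)
    for (i in seq_len(nrow(df))) {
      row <- df[i, , drop = FALSE]
      for (tp in q$template) {
        terms <- vapply(list(tp$s, tp$p, tp$o), function(t) {
          if (startsWith(t, "?")) {
            vn <- var_name(t)
            if (vn %in% names(row)) row[[vn]][1L] else NA_character_
          } else t
        }, character(1))
        if (!anyNA(terms)) { s <- c(s, terms[1]); p <- c(p, terms[2]); o <- c(o, terms[3]) }
      }
    }
    g <- unique(rdf_graph(s, p, o))
    class(g) <- c("rdf_graph", "data.frame")
    return(g)
  }
  if (q$form == "describe") {
    subjects <- character(0)
    if (!is.null(q$where)) {
      df <- eval_group(q$where, graph, graph)
      vars <- if (isTRUE(q$star)) names(df) else vapply(Filter(is.character, q$terms), var_name, character(1))
      vars <- intersect(vars, names(df))
      for (v in vars) subjects <- c(subjects, df[[v]])
    }
    iris <- Filter(function(t) is.character(t) && !startsWith(t, "?"), q$terms)
    subjects <- unique(c(subjects, unlist(iris)))
    out <- graph[graph$s %in% subjects, , drop = FALSE]
    class(out) <- c("rdf_graph", "data.frame")
    return(out)
  }
  stop("unsupported query form: ", q$form)
}

# Canonical multiset fingerprint of a solution table (test helper surface).
solution_multiset <- function(df) {
  if (!nrow(df)) return(character(0))
  cols <- sort(names(df))
  sort(vapply(seq_len(nrow(df)), function(i)
    paste(paste0(cols, "=", ifelse(is.na(unlist(df[i, cols])), "<unbound>", unlist(df[i, cols]))), collapse = "|"),
    character(1)))
}
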