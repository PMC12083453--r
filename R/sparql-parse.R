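# Strict SPARQL 1.1 parser.
#
# Recursive descent over the shared tokenizer, producing an algebra made of
# plain lists. Coverage: SELECT / ASK / CONSTRUCT / DESCRIBE plus the common
# update forms, group graph patterns with OPTIONAL / UNION / MINUS / GRAPH /
# SERVICE / FILTER / BIND / VALUES / subselects, property paths, aggregates
# and expressions. Prefixed names are resolved eagerly, so an undeclared
# prefix is a parse error naming the label (the behaviour the prefix fixer
# relies on).

SPARQL_AGGREGATES <- c("COUNT", "SUM", "MIN", "MAX", "AVG", "SAMPLE", "GROUP_CONCAT")

sparql_error <- function(st, msg) {
  off <- if (st$i <= st$n) st$toks$start[st$i] else nchar(st$text)
  cond <- simpleError(sprintf("SPARQL parse error at line %d: %s", token_line(st$text, off), msg))
  class(cond) <- c("sparql_parse_error", class(cond))
  stop(cond)
}

sq_peek <- function(st, k = 0L) if (st$i + k <= st$n) st$toks[st$i + k, ] else NULL
sq_next <- function(st) { if (st$i > st$n) sparql_error(st, "unexpected end of query"); tok <- st$toks[st$i, ]; st$i <- st$i + 1L; tok }
sq_kw <- function(tok, word) !is.null(tok) && tok$type == "IDENT" && toupper(tok$text) == word
sq_is <- function(tok, txt) !is.null(tok) && tok$text == txt
sq_expect <- function(st, txt) {
  tok <- sq_peek(st)
  if (!sq_is(tok, txt)) sparql_error(st, paste0("expected '", txt, "'"))
  sq_next(st)
}
sq_expect_kw <- function(st, word) {
  tok <- sq_peek(st)
  if (!sq_kw(tok, word)) sparql_error(st, paste0("expected ", word))
  sq_next(st)
}

#' Parse a SPARQL 1.1 query
#'
#' @param text Query text.
#' @param extra_prefixes Named character vector of prefix label -> namespace
#'   made available in addition to the query's own PREFIX declarations
#'   (e.g. from `sh:prefixes` metadata).
#' @return A list of class `sparql_query`: fields include `form`
#'   ("select", "ask", "construct", "describe", "update"), `prefixes`,
#'   `projection`, `where` (the pattern algebra), solution modifiers
#'   (`group_by`, `having`, `order_by`, `limit`, `offset`) and `statements`
#'   (character spans of triple statements, used by the fixer).
#' @export
parse_sparql <- function(text, extra_prefixes = character(0)) {
  toks <- tokenize_rdf(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L; st$n <- nrow(toks); st$text <- text
  st$prefixes <- extra_prefixes
  st$base <- NULL
  st$bcount <- 0L
  st$stmts <- list()

  # prologue
  repeat {
    tok <- sq_peek(st)
    if (sq_kw(tok, "PREFIX")) {
      sq_next(st)
      ns_tok <- sq_next(st)
      if (!ns_tok$type %in% c("PNAME_NS", "PNAME_LN")) sparql_error(st, "expected prefix label")
      label <- sub(":$", "", ns_tok$text)
      iri_tok <- sq_next(st)
      if (iri_tok$type != "IRIREF") sparql_error(st, "expected namespace IRI")
      st$prefixes[[label]] <- substr(iri_tok$text, 2L, nchar(iri_tok$text) - 1L)
    } else if (sq_kw(tok, "BASE")) {
      sq_next(st)
      iri_tok <- sq_next(st)
      st$base <- substr(iri_tok$text, 2L, nchar(iri_tok$text) - 1L)
    } else break
  }

  tok <- sq_peek(st)
  if (is.null(tok)) sparql_error(st, "empty query")
  kw <- if (tok$type == "IDENT") toupper(tok$text) else ""
  q <- switch(kw,
    SELECT = parse_select_query(st, top = TRUE),
    ASK = parse_ask_query(st),
    CONSTRUCT = parse_construct_query(st),
    DESCRIBE = parse_describe_query(st),
    INSERT = , DELETE = , WITH = , LOAD = , CLEAR = , DROP = , CREATE = , COPY = , MOVE = , ADD =
      parse_update_query(st),
    sparql_error(st, paste0("expected a query form, found '", tok$text, "'")))
  if (st$i <= st$n) {
    tok <- sq_peek(st)
    if (q$form == "update" && sq_is(tok, ";")) {
      # multi-operation updates: accept and skip the remainder unparsed
      st$i <- st$n + 1L
    } else sparql_error(st, paste0("unexpected trailing token '", tok$text, "'"))
  }
  q$prefixes <- st$prefixes
  q$base <- st$base
  q$statements <- st$stmts
  class(q) <- "sparql_query"
  q
}

#' @export
print.sparql_query <- function(x, ...) {
  cat("<sparql_query> form:", x$form, "\n")
  invisible(x)
}

sq_fresh_bnode <- function(st) { st$bcount <- st$bcount + 1L; rdf_bnode(paste0("q", st$bcount)) }

sq_resolve_pname <- function(st, txt) {
  idx <- regexpr(":", txt, fixed = TRUE)
  label <- substr(txt, 1L, idx - 1L)
  local <- substr(txt, idx + 1L, nchar(txt))
  if (!label %in% names(st$prefixes)) {
    cond <- simpleError(paste0("undeclared prefix '", label, ":'"))
    class(cond) <- c("sparql_unknown_prefix", "sparql_parse_error", class(cond))
    attr(cond$message, "label") <- label
    cond$label <- label
    stop(cond)
  }
  rdf_iri(paste0(st$prefixes[[label]], local))
}

sq_iri_from_token <- function(st, tok) {
  switch(tok$type,
    IRIREF = rdf_iri(substr(tok$text, 2L, nchar(tok$text) - 1L)),
    PNAME_LN = sq_resolve_pname(st, tok$text),
    PNAME_NS = sq_resolve_pname(st, tok$text),
    sparql_error(st, paste0("expected IRI, found '", tok$text, "'")))
}

## --------------------------------------------------------------------------
## query forms

parse_dataset_clauses <- function(st) {
  default <- character(0); named <- character(0)
  while (sq_kw(sq_peek(st), "FROM")) {
    sq_next(st)
    if (sq_kw(sq_peek(st), "NAMED")) {
      sq_next(st)
      named <- c(named, iri_value(sq_iri_from_token(st, sq_next(st))))
    } else default <- c(default, iri_value(sq_iri_from_token(st, sq_next(st))))
  }
  list(default = default, named = named)
}

parse_select_query <- function(st, top = FALSE) {
  sq_expect_kw(st, "SELECT")
  distinct <- FALSE; reduced <- FALSE
  if (sq_kw(sq_peek(st), "DISTINCT")) { distinct <- TRUE; sq_next(st) }
  else if (sq_kw(sq_peek(st), "REDUCED")) { reduced <- TRUE; sq_next(st) }
  projection <- list()
  star <- FALSE
  if (sq_is(sq_peek(st), "*")) { star <- TRUE; sq_next(st) }
  else {
    repeat {
      tok <- sq_peek(st)
      if (!is.null(tok) && tok$type == "VAR") {
        sq_next(st)
        projection[[length(projection) + 1L]] <- list(var = normalize_var(tok$text))
      } else if (sq_is(tok, "(")) {
        sq_next(st)
        expr <- parse_expression(st)
        sq_expect_kw(st, "AS")
        var_tok <- sq_next(st)
        if (var_tok$type != "VAR") sparql_error(st, "expected variable after AS")
        sq_expect(st, ")")
        projection[[length(projection) + 1L]] <- list(var = normalize_var(var_tok$text), expr = expr)
      } else break
    }
    if (!length(projection)) sparql_error(st, "empty SELECT clause")
  }
  dataset <- if (top) parse_dataset_clauses(st) else list(default = character(0), named = character(0))
  if (sq_kw(sq_peek(st), "WHERE")) sq_next(st)
  where <- parse_ggp(st)
  mods <- parse_solution_modifiers(st, allow_values = top)
  c(list(form = "select", distinct = distinct, reduced = reduced, star = star,
         projection = projection, dataset = dataset, where = where), mods)
}

parse_ask_query <- function(st) {
  sq_expect_kw(st, "ASK")
  dataset <- parse_dataset_clauses(st)
  if (sq_kw(sq_peek(st), "WHERE")) sq_next(st)
  where <- parse_ggp(st)
  mods <- parse_solution_modifiers(st, allow_values = TRUE)
  c(list(form = "ask", dataset = dataset, where = where), mods)
}

parse_construct_query <- function(st) {
  sq_expect_kw(st, "CONSTRUCT")
  template <- NULL
  if (sq_is(sq_peek(st), "{")) {
    template <- parse_construct_template(st)
    dataset <- parse_dataset_clauses(st)
    if (sq_kw(sq_peek(st), "WHERE")) sq_next(st)
    where <- parse_ggp(st)
  } else {
    # CONSTRUCT WHERE { triples } short form
    dataset <- parse_dataset_clauses(st)
    sq_expect_kw(st, "WHERE")
    where <- parse_ggp(st)
    template <- Filter(function(e) e$type == "tp", where$elts)
  }
  mods <- parse_solution_modifiers(st, allow_values = TRUE)
  c(list(form = "construct", template = template, dataset = dataset, where = where), mods)
}

parse_construct_template <- function(st) {
  grp <- parse_ggp(st)
  bad <- Filter(function(e) e$type != "tp", grp$elts)
  if (length(bad)) sparql_error(st, "CONSTRUCT template may only contain triple patterns")
  grp$elts
}

parse_describe_query <- function(st) {
  sq_expect_kw(st, "DESCRIBE")
  terms <- list()
  star <- FALSE
  if (sq_is(sq_peek(st), "*")) { star <- TRUE; sq_next(st) }
  else {
    repeat {
      tok <- sq_peek(st)
      if (!is.null(tok) && tok$type == "VAR") { sq_next(st); terms[[length(terms) + 1L]] <- normalize_var(tok$text) }
      else if (!is.null(tok) && tok$type %in% c("IRIREF", "PNAME_LN", "PNAME_NS"))
        terms[[length(terms) + 1L]] <- sq_iri_from_token(st, sq_next(st))
      else break
    }
    if (!length(terms)) sparql_error(st, "DESCRIBE needs a variable, an IRI, or *")
  }
  dataset <- parse_dataset_clauses(st)
  where <- NULL
  if (sq_kw(sq_peek(st), "WHERE")) { sq_next(st); where <- parse_ggp(st) }
  else if (sq_is(sq_peek(st), "{")) where <- parse_ggp(st)
  mods <- parse_solution_modifiers(st, allow_values = TRUE)
  c(list(form = "describe", star = star, terms = terms, dataset = dataset, where = where), mods)
}

parse_update_query <- function(st) {
  tok <- sq_peek(st)
  kw <- toupper(tok$text)
  where <- NULL; template_ins <- NULL; template_del <- NULL
  if (kw %in% c("LOAD", "CLEAR", "DROP", "CREATE", "COPY", "MOVE", "ADD")) {
    # management operations: consume remaining tokens without interpretation
    st$i <- st$n + 1L
    return(list(form = "update", operation = tolower(kw), where = NULL))
  }
  if (kw == "WITH") { sq_next(st); sq_iri_from_token(st, sq_next(st)) }
  tok <- sq_peek(st)
  kw <- toupper(tok$text)
  if (kw == "DELETE") {
    sq_next(st)
    if (sq_kw(sq_peek(st), "DATA")) { sq_next(st); template_del <- parse_construct_template(st); }
    else if (sq_kw(sq_peek(st), "WHERE")) { sq_next(st); where <- parse_ggp(st) }
    else template_del <- parse_construct_template(st)
  }
  if (sq_kw(sq_peek(st), "INSERT")) {
    sq_next(st)
    if (sq_kw(sq_peek(st), "DATA")) { sq_next(st); template_ins <- parse_construct_template(st) }
    else template_ins <- parse_construct_template(st)
  }
  while (sq_kw(sq_peek(st), "USING")) {
    sq_next(st)
    if (sq_kw(sq_peek(st), "NAMED")) sq_next(st)
    sq_iri_from_token(st, sq_next(st))
  }
  if (sq_kw(sq_peek(st), "WHERE")) { sq_next(st); where <- parse_ggp(st) }
  list(form = "update", operation = "modify", insert = template_ins, delete = template_del, where = where)
}

parse_solution_modifiers <- function(st, allow_values = FALSE) {
  group_by <- NULL; having <- NULL; order_by <- NULL
  limit <- NA_integer_; offset <- NA_integer_; values <- NULL
  if (sq_kw(sq_peek(st), "GROUP")) {
    sq_next(st); sq_expect_kw(st, "BY")
    group_by <- list()
    repeat {
      tok <- sq_peek(st)
      if (!is.null(tok) && tok$type == "VAR") { sq_next(st); group_by[[length(group_by) + 1L]] <- normalize_var(tok$text) }
      else if (sq_is(tok, "(")) {
        sq_next(st)
        expr <- parse_expression(st)
        v <- NULL
        if (sq_kw(sq_peek(st), "AS")) { sq_next(st); v <- normalize_var(sq_next(st)$text) }
        sq_expect(st, ")")
        group_by[[length(group_by) + 1L]] <- list(expr = expr, var = v)
      } else if (!is.null(tok) && tok$type == "IDENT" && sq_is(sq_peek(st, 1L), "(") &&
                 !toupper(tok$text) %in% c("HAVING", "ORDER", "LIMIT", "OFFSET", "VALUES")) {
        group_by[[length(group_by) + 1L]] <- list(expr = parse_primary_expression(st), var = NULL)
      } else break
    }
    if (!length(group_by)) sparql_error(st, "empty GROUP BY")
  }
  if (sq_kw(sq_peek(st), "HAVING")) {
    sq_next(st)
    having <- list(parse_constraint(st))
    while (sq_is(sq_peek(st), "(") || (!is.null(sq_peek(st)) && sq_peek(st)$type == "IDENT" &&
           toupper(sq_peek(st)$text) %in% c(SPARQL_AGGREGATES, "REGEX", "CONTAINS", "BOUND")))
      having[[length(having) + 1L]] <- parse_constraint(st)
  }
  if (sq_kw(sq_peek(st), "ORDER")) {
    sq_next(st); sq_expect_kw(st, "BY")
    order_by <- list()
    repeat {
      tok <- sq_peek(st)
      if (sq_kw(tok, "ASC") || sq_kw(tok, "DESC")) {
        dir <- toupper(sq_next(st)$text)
        sq_expect(st, "(")
        expr <- parse_expression(st)
        sq_expect(st, ")")
        order_by[[length(order_by) + 1L]] <- list(dir = dir, expr = expr)
      } else if (!is.null(tok) && tok$type == "VAR") {
        sq_next(st)
        order_by[[length(order_by) + 1L]] <- list(dir = "ASC", expr = normalize_var(tok$text))
      } else if (sq_is(tok, "(")) {
        sq_next(st); expr <- parse_expression(st); sq_expect(st, ")")
        order_by[[length(order_by) + 1L]] <- list(dir = "ASC", expr = expr)
      } else break
    }
    if (!length(order_by)) sparql_error(st, "empty ORDER BY")
  }
  # LIMIT and OFFSET in either order
  for (k in 1:2) {
    if (sq_kw(sq_peek(st), "LIMIT")) {
      sq_next(st)
      tok <- sq_next(st)
      if (tok$type != "INTEGER") sparql_error(st, "LIMIT expects an integer")
      limit <- as.integer(tok$text)
    } else if (sq_kw(sq_peek(st), "OFFSET")) {
      sq_next(st)
      tok <- sq_next(st)
      if (tok$type != "INTEGER") sparql_error(st, "OFFSET expects an integer")
      offset <- as.integer(tok$text)
    }
  }
  if (allow_values && sq_kw(sq_peek(st), "VALUES")) values <- parse_values(st)
  list(group_by = group_by, having = having, order_by = order_by,
       limit = limit, offset = offset, values = values)
}

## --------------------------------------------------------------------------
## group graph patterns

parse_ggp <- function(st) {
  sq_expect(st, "{")
  if (sq_kw(sq_peek(st), "SELECT")) {
    sub <- parse_select_query(st, top = FALSE)
    class(sub) <- "sparql_query"
    sq_expect(st, "}")
    return(list(type = "group", elts = list(list(type = "subselect", query = sub))))
  }
  elts <- list()
  repeat {
    tok <- sq_peek(st)
    if (is.null(tok)) sparql_error(st, "unterminated group graph pattern")
    if (sq_is(tok, "}")) { sq_next(st); break }
    if (sq_is(tok, ".")) { sq_next(st); next }
    if (sq_kw(tok, "OPTIONAL")) {
      sq_next(st)
      elts[[length(elts) + 1L]] <- list(type = "optional", group = parse_ggp(st))
    } else if (sq_kw(tok, "MINUS")) {
      sq_next(st)
      elts[[length(elts) + 1L]] <- list(type = "minus", group = parse_ggp(st))
    } else if (sq_kw(tok, "FILTER")) {
      sq_next(st)
      elts[[length(elts) + 1L]] <- list(type = "filter", expr = parse_constraint(st))
    } else if (sq_kw(tok, "BIND")) {
      sq_next(st)
      sq_expect(st, "(")
      expr <- parse_expression(st)
      sq_expect_kw(st, "AS")
      var_tok <- sq_next(st)
      if (var_tok$type != "VAR") sparql_error(st, "expected variable after AS")
      sq_expect(st, ")")
      elts[[length(elts) + 1L]] <- list(type = "bind", expr = expr, var = normalize_var(var_tok$text))
    } else if (sq_kw(tok, "VALUES")) {
      elts[[length(elts) + 1L]] <- parse_values(st)
    } else if (sq_kw(tok, "SERVICE")) {
      sq_next(st)
      silent <- FALSE
      if (sq_kw(sq_peek(st), "SILENT")) { silent <- TRUE; sq_next(st) }
      ep_tok <- sq_next(st)
      endpoint <- if (ep_tok$type == "VAR") normalize_var(ep_tok$text) else sq_iri_from_token(st, ep_tok)
      elts[[length(elts) + 1L]] <- list(type = "service", silent = silent, endpoint = endpoint,
                                        group = parse_ggp(st))
    } else if (sq_kw(tok, "GRAPH")) {
      sq_next(st)
      g_tok <- sq_next(st)
      gname <- if (g_tok$type == "VAR") normalize_var(g_tok$text) else sq_iri_from_token(st, g_tok)
      elts[[length(elts) + 1L]] <- list(type = "graph", name = gname, group = parse_ggp(st))
    } else if (sq_is(tok, "{")) {
      first <- parse_ggp_or_subselect(st)
      branches <- list(first)
      while (sq_kw(sq_peek(st), "UNION")) {
        sq_next(st)
        branches[[length(branches) + 1L]] <- parse_ggp_or_subselect(st)
      }
      elts[[length(elts) + 1L]] <- if (length(branches) == 1L) list(type = "nested", group = first)
                                   else list(type = "union", branches = branches)
    } else {
      elts <- c(elts, parse_triples_statement(st))
    }
  }
  list(type = "group", elts = elts)
}

parse_ggp_or_subselect <- function(st) parse_ggp(st)

parse_values <- function(st) {
  sq_expect_kw(st, "VALUES")
  tok <- sq_peek(st)
  vars <- character(0)
  if (!is.null(tok) && tok$type == "VAR") {
    vars <- normalize_var(sq_next(st)$text)
    sq_expect(st, "{")
    rows <- list()
    while (!sq_is(sq_peek(st), "}")) rows[[length(rows) + 1L]] <- parse_values_term(st)
    sq_next(st)
    return(list(type = "values", vars = vars, rows = lapply(rows, function(r) stats::setNames(r, vars))))
  }
  sq_expect(st, "(")
  while (!sq_is(sq_peek(st), ")")) vars <- c(vars, normalize_var(sq_next(st)$text))
  sq_next(st)
  sq_expect(st, "{")
  rows <- list()
  while (!sq_is(sq_peek(st), "}")) {
    sq_expect(st, "(")
    row <- character(0)
    while (!sq_is(sq_peek(st), ")")) row <- c(row, parse_values_term(st))
    sq_next(st)
    if (length(row) != length(vars)) sparql_error(st, "VALUES row arity mismatch")
    rows[[length(rows) + 1L]] <- stats::setNames(row, vars)
  }
  sq_next(st)
  list(type = "values", vars = vars, rows = rows)
}

parse_values_term <- function(st) {
  tok <- sq_peek(st)
  if (sq_kw(tok, "UNDEF")) { sq_next(st); return(NA_character_) }
  parse_graph_term(st)
}

parse_graph_term <- function(st) {
  tok <- sq_next(st)
  if (tok$type %in% c("IRIREF", "PNAME_LN", "PNAME_NS")) return(sq_iri_from_token(st, tok))
  if (tok$type %in% c("STRING", "STRING1", "STRING_LONG")) {
    value <- string_token_value(tok$text)
    nxt <- sq_peek(st)
    if (!is.null(nxt) && nxt$type == "LANGTAG") {
      sq_next(st)
      return(rdf_literal(value, lang = substr(nxt$text, 2L, nchar(nxt$text))))
    }
    if (sq_is(nxt, "^^")) {
      sq_next(st)
      return(rdf_literal(value, datatype = iri_value(sq_iri_from_token(st, sq_next(st)))))
    }
    return(rdf_literal(value))
  }
  if (tok$type %in% c("INTEGER", "DECIMAL", "DOUBLE")) return(number_token_literal(tok$type, tok$text))
  if (tok$type == "IDENT" && tok$text %in% c("true", "false"))
    return(paste0('"', tok$text, '"^^<', XSD, "boolean>"))
  if (tok$type == "BNODE") return(tok$text)
  sparql_error(st, paste0("expected an RDF term, found '", tok$text, "'"))
}

normalize_var <- function(txt) paste0("?", sub("^[?$]", "", txt))

## triples with spans ---------------------------------------------------------

# Parses one TriplesSameSubjectPath statement (through the optional '.') and
# returns the list of tp elements. Records a statement-span entry in st$stmts.
parse_triples_statement <- function(st) {
  start_tok <- sq_peek(st)
  stmt_start <- start_tok$start
  tps <- list()
  pos <- list()
  subj_info <- parse_tp_node(st, tps_env = NULL)
  subj <- subj_info$node
  extra_tps <- subj_info$tps       # from blank node property lists
  repeat {
    po_start <- sq_peek(st)$start
    pred <- parse_path(st)
    n_before <- length(tps)
    repeat {
      obj_info <- parse_tp_node(st)
      tps[[length(tps) + 1L]] <- list(type = "tp", s = subj, p = pred, o = obj_info$node)
      if (length(obj_info$tps)) tps <- c(tps, obj_info$tps)
      if (sq_is(sq_peek(st), ",")) sq_next(st) else break
    }
    po_end <- st$toks$end[st$i - 1L]
    pred_iri <- if (is.character(pred) && term_type(pred) == "iri") iri_value(pred) else NA_character_
    pos[[length(pos) + 1L]] <- list(span = c(po_start, po_end), pred = pred_iri,
                                    n_tp = length(tps) - n_before)
    if (sq_is(sq_peek(st), ";")) {
      sq_next(st)
      while (sq_is(sq_peek(st), ";")) sq_next(st)
      tok <- sq_peek(st)
      if (is.null(tok) || tok$text %in% c(".", "}")) break
      if (tok$type %in% c("IDENT") && !tok$text == "a" &&
          toupper(tok$text) %in% c("OPTIONAL", "FILTER", "BIND", "MINUS", "VALUES", "SERVICE", "GRAPH", "UNION"))
        break
      next
    }
    break
  }
  stmt_end <- st$toks$end[st$i - 1L]
  if (sq_is(sq_peek(st), ".")) { tok <- sq_next(st); stmt_end <- tok$end }
  subj_iri <- if (is.character(subj) && length(subj) == 1L && term_type(subj) == "iri")
    iri_value(subj) else NA_character_
  st$stmts[[length(st$stmts) + 1L]] <- list(span = c(stmt_start, stmt_end),
                                            subject = subj_iri, pos = pos)
  c(tps, extra_tps)
}

# Parses a subject/object node: term, variable, [] or blank node property list.
# Returns list(node=, tps=list of extra tps generated by property lists).
parse_tp_node <- function(st, tps_env = NULL) {
  tok <- sq_peek(st)
  if (is.null(tok)) sparql_error(st, "unexpected end of query in triple pattern")
  if (tok$type == "VAR") { sq_next(st); return(list(node = normalize_var(tok$text), tps = list())) }
  if (sq_is(tok, "[")) {
    sq_next(st)
    node <- sq_fresh_bnode(st)
    tps <- list()
    if (!sq_is(sq_peek(st), "]")) {
      repeat {
        pred <- parse_path(st)
        repeat {
          obj_info <- parse_tp_node(st)
          tps[[length(tps) + 1L]] <- list(type = "tp", s = node, p = pred, o = obj_info$node)
          if (length(obj_info$tps)) tps <- c(tps, obj_info$tps)
          if (sq_is(sq_peek(st), ",")) sq_next(st) else break
        }
        if (sq_is(sq_peek(st), ";")) {
          sq_next(st)
          if (sq_is(sq_peek(st), "]")) break
        } else break
      }
    }
    sq_expect(st, "]")
    return(list(node = node, tps = tps))
  }
  list(node = parse_graph_term(st), tps = list())
}

## property paths -------------------------------------------------------------

parse_path <- function(st) {
  tok <- sq_peek(st)
  if (!is.null(tok) && tok$type == "VAR") { sq_next(st); return(normalize_var(tok$text)) }
  path <- parse_path_alternative(st)
  path
}

parse_path_alternative <- function(st) {
  first <- parse_path_sequence(st)
  if (!sq_is(sq_peek(st), "|")) return(first)
  elts <- list(first)
  while (sq_is(sq_peek(st), "|")) {
    sq_next(st)
    elts[[length(elts) + 1L]] <- parse_path_sequence(st)
  }
  list(type = "path", op = "alt", elts = elts)
}

parse_path_sequence <- function(st) {
  first <- parse_path_elt_or_inverse(st)
  if (!sq_is(sq_peek(st), "/")) return(first)
  elts <- list(first)
  while (sq_is(sq_peek(st), "/")) {
    sq_next(st)
    elts[[length(elts) + 1L]] <- parse_path_elt_or_inverse(st)
  }
  list(type = "path", op = "seq", elts = elts)
}

parse_path_elt_or_inverse <- function(st) {
  if (sq_is(sq_peek(st), "^")) {
    sq_next(st)
    return(list(type = "path", op = "inv", elts = list(parse_path_elt(st))))
  }
  parse_path_elt(st)
}

parse_path_elt <- function(st) {
  prim <- parse_path_primary(st)
  tok <- sq_peek(st)
  if (sq_is(tok, "*") || sq_is(tok, "+") || sq_is(tok, "?")) {
    sq_next(st)
    return(list(type = "path", op = "mod", mod = tok$text, elts = list(prim)))
  }
  prim
}

parse_path_primary <- function(st) {
  tok <- sq_peek(st)
  if (sq_is(tok, "(")) {
    sq_next(st)
    p <- parse_path_alternative(st)
    sq_expect(st, ")")
    return(p)
  }
  if (sq_is(tok, "!")) {
    sq_next(st)
    inner <- parse_path_primary(st)
    return(list(type = "path", op = "neg", elts = list(inner)))
  }
  if (tok$type == "IDENT" && tok$text == "a") {
    sq_next(st)
    return(rdf_iri(paste0(RDF_NS, "type")))
  }
  sq_iri_from_token(st, sq_next(st))
}

path_is_simple <- function(p) is.character(p)

## expressions ----------------------------------------------------------------

parse_constraint <- function(st) {
  tok <- sq_peek(st)
  if (sq_is(tok, "(")) {
    sq_next(st)
    expr <- parse_expression(st)
    sq_expect(st, ")")
    return(expr)
  }
  parse_primary_expression(st)
}

parse_expression <- function(st) parse_or_expression(st)

parse_or_expression <- function(st) {
  lhs <- parse_and_expression(st)
  while (sq_is(sq_peek(st), "||")) {
    sq_next(st)
    lhs <- list(type = "op", op = "||", args = list(lhs, parse_and_expression(st)))
  }
  lhs
}

parse_and_expression <- function(st) {
  lhs <- parse_relational_expression(st)
  while (sq_is(sq_peek(st), "&&")) {
    sq_next(st)
    lhs <- list(type = "op", op = "&&", args = list(lhs, parse_relational_expression(st)))
  }
  lhs
}

parse_relational_expression <- function(st) {
  lhs <- parse_additive_expression(st)
  tok <- sq_peek(st)
  if (!is.null(tok) && tok$text %in% c("=", "!=", "<", ">", "<=", ">=")) {
    op <- sq_next(st)$text
    return(list(type = "op", op = op, args = list(lhs, parse_additive_expression(st))))
  }
  if (sq_kw(tok, "IN") || (sq_kw(tok, "NOT") && sq_kw(sq_peek(st, 1L), "IN"))) {
    negated <- sq_kw(tok, "NOT")
    sq_next(st)
    if (negated) sq_next(st)
    sq_expect(st, "(")
    items <- list()
    while (!sq_is(sq_peek(st), ")")) {
      items[[length(items) + 1L]] <- parse_expression(st)
      if (sq_is(sq_peek(st), ",")) sq_next(st)
    }
    sq_next(st)
    return(list(type = "in", negated = negated, lhs = lhs, items = items))
  }
  lhs
}

parse_additive_expression <- function(st) {
  lhs <- parse_multiplicative_expression(st)
  repeat {
    tok <- sq_peek(st)
    if (sq_is(tok, "+") || sq_is(tok, "-")) {
      op <- sq_next(st)$text
      lhs <- list(type = "op", op = op, args = list(lhs, parse_multiplicative_expression(st)))
    } else if (!is.null(tok) && tok$type %in% c("INTEGER", "DECIMAL", "DOUBLE") &&
               substr(tok$text, 1L, 1L) %in% c("+", "-")) {
      # signed number token absorbing the operator
      sq_next(st)
      lhs <- list(type = "op", op = substr(tok$text, 1L, 1L),
                  args = list(lhs, number_token_literal(tok$type, sub("^[+-]", "", tok$text))))
    } else break
  }
  lhs
}

parse_multiplicative_expression <- function(st) {
  lhs <- parse_unary_expression(st)
  repeat {
    tok <- sq_peek(st)
    if (sq_is(tok, "*") || sq_is(tok, "/")) {
      op <- sq_next(st)$text
      lhs <- list(type = "op", op = op, args = list(lhs, parse_unary_expression(st)))
    } else break
  }
  lhs
}

parse_unary_expression <- function(st) {
  tok <- sq_peek(st)
  if (sq_is(tok, "!")) {
    sq_next(st)
    return(list(type = "op", op = "!", args = list(parse_unary_expression(st))))
  }
  if (sq_is(tok, "-")) {
    sq_next(st)
    return(list(type = "op", op = "uminus", args = list(parse_unary_expression(st))))
  }
  if (sq_is(tok, "+")) sq_next(st)
  parse_primary_expression(st)
}

parse_primary_expression <- function(st) {
  tok <- sq_peek(st)
  if (is.null(tok)) sparql_error(st, "unexpected end of expression")
  if (sq_is(tok, "(")) {
    sq_next(st)
    expr <- parse_expression(st)
    sq_expect(st, ")")
    return(expr)
  }
  if (tok$type == "VAR") { sq_next(st); return(normalize_var(tok$text)) }
  if (tok$type == "IDENT") {
    up <- toupper(tok$text)
    if (up == "EXISTS") {
      sq_next(st)
      return(list(type = "exists", negated = FALSE, group = parse_ggp(st)))
    }
    if (up == "NOT" && sq_kw(sq_peek(st, 1L), "EXISTS")) {
      sq_next(st); sq_next(st)
      return(list(type = "exists", negated = TRUE, group = parse_ggp(st)))
    }
    if (tok$text %in% c("true", "false")) {
      sq_next(st)
      return(paste0('"', tok$text, '"^^<', XSD, "boolean>"))
    }
    if (sq_is(sq_peek(st, 1L), "(")) return(parse_function_call(st))
    sparql_error(st, paste0("unexpected identifier '", tok$text, "' in expression"))
  }
  if (tok$type %in% c("PNAME_LN", "PNAME_NS", "IRIREF")) {
    term <- sq_iri_from_token(st, sq_next(st))
    if (sq_is(sq_peek(st), "(")) {
      args <- parse_arg_list(st)
      return(list(type = "call", name = iri_value(term), iri_function = TRUE,
                  distinct = FALSE, args = args))
    }
    return(term)
  }
  if (tok$type %in% c("STRING", "STRING1", "STRING_LONG", "INTEGER", "DECIMAL", "DOUBLE"))
    return(parse_graph_term(st))
  sparql_error(st, paste0("unexpected token '", tok$text, "' in expression"))
}

parse_function_call <- function(st) {
  name_tok <- sq_next(st)
  name <- toupper(name_tok$text)
  sq_expect(st, "(")
  distinct <- FALSE
  if (sq_kw(sq_peek(st), "DISTINCT")) { distinct <- TRUE; sq_next(st) }
  args <- list()
  separator <- NULL
  if (sq_is(sq_peek(st), "*")) {
    sq_next(st)
    args <- list("*")
  } else if (!sq_is(sq_peek(st), ")")) {
    repeat {
      args[[length(args) + 1L]] <- parse_expression(st)
      tok <- sq_peek(st)
      if (sq_is(tok, ",")) { sq_next(st); next }
      if (sq_is(tok, ";")) {   # GROUP_CONCAT(...; SEPARATOR="x")
        sq_next(st)
        sq_expect_kw(st, "SEPARATOR")
        sq_expect(st, "=")
        sep_tok <- sq_next(st)
        separator <- string_token_value(sep_tok$text)
        next
      }
      break
    }
  }
  sq_expect(st, ")")
  list(type = "call", name = name, distinct = distinct, args = args,
       separator = separator, aggregate = name %in% SPARQL_AGGREGATES)
}

## --------------------------------------------------------------------------
## algebra -> text (used for the dual-parse redundancy check and by the fixer)

#' Serialize a parsed query back to SPARQL text
#'
#' The output is a canonical rendering of the algebra (one pattern per line,
#' IRIs in full); it parses under [parse_sparql()] and is algebra-equivalent
#' to the input query.
#'
#' @param q A `sparql_query`.
#' @return SPARQL text.
#' @export
sparql_serialize <- function(q) {
  out <- character(0)
  if (q$form == "update") stop("serialization of update operations is not supported")
  if (q$form == "select") {
    proj <- if (isTRUE(q$star)) "*" else paste(vapply(q$projection, function(p) {
      if (is.null(p$expr)) p$var else paste0("(", serialize_expr(p$expr), " AS ", p$var, ")")
    }, character(1)), collapse = " ")
    out <- c(out, paste0("SELECT ", if (isTRUE(q$distinct)) "DISTINCT " else if (isTRUE(q$reduced)) "REDUCED " else "", proj))
  } else if (q$form == "ask") {
    out <- c(out, "ASK")
  } else if (q$form == "construct") {
    out <- c(out, "CONSTRUCT {", vapply(q$template, function(tp)
      paste0("  ", serialize_tp(tp)), character(1)), "}")
  } else if (q$form == "describe") {
    terms <- if (isTRUE(q$star)) "*" else paste(vapply(q$terms, function(t) t, character(1)), collapse = " ")
    out <- c(out, paste0("DESCRIBE ", terms))
  }
  if (!is.null(q$dataset)) {
    out <- c(out, vapply(q$dataset$default, function(iri) paste0("FROM <", iri, ">"), character(1)),
             vapply(q$dataset$named, function(iri) paste0("FROM NAMED <", iri, ">"), character(1)))
  }
  if (!is.null(q$where)) out <- c(out, "WHERE", serialize_group(q$where, 0L))
  out <- c(out, serialize_modifiers(q))
  paste(out, collapse = "\n")
}

serialize_modifiers <- function(q) {
  out <- character(0)
  if (!is.null(q$group_by)) {
    gb <- vapply(q$group_by, function(g) {
      if (is.character(g)) g
      else if (!is.null(g$var)) paste0("(", serialize_expr(g$expr), " AS ", g$var, ")")
      else paste0("(", serialize_expr(g$expr), ")")
    }, character(1))
    out <- c(out, paste("GROUP BY", paste(gb, collapse = " ")))
  }
  if (!is.null(q$having))
    out <- c(out, paste("HAVING", paste(vapply(q$having, function(h)
      paste0("(", serialize_expr(h), ")"), character(1)), collapse = " ")))
  if (!is.null(q$order_by))
    out <- c(out, paste("ORDER BY", paste(vapply(q$order_by, function(o)
      paste0(o$dir, "(", serialize_expr(o$expr), ")"), character(1)), collapse = " ")))
  if (!is.null(q$limit) && !is.na(q$limit)) out <- c(out, paste("LIMIT", q$limit))
  if (!is.null(q$offset) && !is.na(q$offset)) out <- c(out, paste("OFFSET", q$offset))
  if (!is.null(q$values)) out <- c(out, serialize_element(q$values, 0L))
  out
}

indent_str <- function(d) strrep("  ", d)

serialize_group <- function(group, d) {
  lines <- c(paste0(indent_str(d), "{"))
  for (e in group$elts) lines <- c(lines, serialize_element(e, d + 1L))
  c(lines, paste0(indent_str(d), "}"))
}

serialize_element <- function(e, d) {
  ind <- indent_str(d)
  switch(e$type,
    tp = paste0(ind, serialize_tp(e)),
    filter = paste0(ind, "FILTER (", serialize_expr(e$expr), ")"),
    bind = paste0(ind, "BIND (", serialize_expr(e$expr), " AS ", e$var, ")"),
    optional = c(paste0(ind, "OPTIONAL"), serialize_group(e$group, d)),
    minus = c(paste0(ind, "MINUS"), serialize_group(e$group, d)),
    nested = serialize_group(e$group, d),
    union = {
      parts <- lapply(e$branches, serialize_group, d = d)
      out <- parts[[1L]]
      for (b in parts[-1L]) out <- c(out, paste0(ind, "UNION"), b)
      out
    },
    service = c(paste0(ind, "SERVICE ", if (isTRUE(e$silent)) "SILENT " else "",
                       if (startsWith(e$endpoint, "?")) e$endpoint else e$endpoint),
                serialize_group(e$group, d)),
    graph = c(paste0(ind, "GRAPH ", e$name), serialize_group(e$group, d)),
    subselect = c(paste0(ind, "{"),
                  paste0(indent_str(d + 1L), strsplit(sparql_serialize(e$query), "\n")[[1]]),
                  paste0(ind, "}")),
    values = {
      hdr <- paste0(ind, "VALUES (", paste(e$vars, collapse = " "), ") {")
      rows <- vapply(e$rows, function(r)
        paste0(indent_str(d + 1L), "(", paste(ifelse(is.na(r), "UNDEF", r), collapse = " "), ")"),
        character(1))
      c(hdr, rows, paste0(ind, "}"))
    },
    stop("unknown pattern element: ", e$type))
}

serialize_tp <- function(tp) paste0(serialize_path_node(tp$s), " ", serialize_path(tp$p), " ",
                                    serialize_path_node(tp$o), " .")

serialize_path_node <- function(x) x

serialize_path <- function(p) {
  if (is.character(p)) return(p)
  switch(p$op,
    seq = paste(vapply(p$elts, serialize_path_wrapped, character(1)), collapse = "/"),
    alt = paste(vapply(p$elts, serialize_path_wrapped, character(1)), collapse = "|"),
    inv = paste0("^", serialize_path_wrapped(p$elts[[1L]])),
    mod = paste0(serialize_path_wrapped(p$elts[[1L]]), p$mod),
    neg = paste0("!", serialize_path_wrapped(p$elts[[1L]])),
    stop("unknown path operator: ", p$op))
}

serialize_path_wrapped <- function(p) {
  if (is.character(p)) return(p)
  paste0("(", serialize_path(p), ")")
}

serialize_expr <- function(e) {
  if (is.character(e)) return(e)
  switch(e$type,
    op = {
      if (e$op == "!") paste0("!(", serialize_expr(e$args[[1L]]), ")")
      else if (e$op == "uminus") paste0("-(", serialize_expr(e$args[[1L]]), ")")
      else paste0("(", serialize_expr(e$args[[1L]]), " ", e$op, " ", serialize_expr(e$args[[2L]]), ")")
    },
    call = {
      name <- if (isTRUE(e$iri_function)) paste0("<", e$name, ">") else e$name
      args <- vapply(e$args, function(a) if (identical(a, "*")) "*" else serialize_expr(a), character(1))
      sep <- if (!is.null(e$separator)) paste0("; SEPARATOR=", '"', escape_string(e$separator), '"') else ""
      paste0(name, "(", if (isTRUE(e$distinct)) "DISTINCT " else "", paste(args, collapse = ", "), sep, ")")
    },
    "in" = paste0(serialize_expr(e$lhs), if (e$negated) " NOT IN (" else " IN (",
                  paste(vapply(e$items, serialize_expr, character(1)), collapse = ", "), ")"),
    exists = paste0(if (e$negated) "NOT EXISTS " else "EXISTS ",
                    paste(serialize_group(e$group, 0L), collapse = "\n")),
    stop("unknown expression node: ", e$type))
}
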