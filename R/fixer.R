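# Rewriting vendor-extended queries into standard SPARQL 1.1.
#
# Three fixes, applied in pipeline order by fix_query():
#   1. add_missing_prefixes()     prepend PREFIX declarations resolved from a
#                                 registry (token-level scan: a query missing
#                                 prefixes does not parse, so no parse is
#                                 required here)
#   2. rewrite_named_subqueries() inline the Blazegraph/Anzo
#                                 `WITH { ... } AS %name` / `INCLUDE %name`
#                                 extension as standard nested subselects
#   3. strip_query_hints()        remove "magic" engine-hint triple patterns
#                                 (Blazegraph / AWS Neptune namespaces), which
#                                 match no data on other engines

DEFAULT_HINT_NAMESPACES <- c(
  "http://www.bigdata.com/queryHints#",
  "http://aws.amazon.com/neptune/vocab/v01/QueryHints#")

DEFAULT_COMMON_PREFIXES <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd = "http://www.w3.org/2001/XMLSchema#",
  owl = "http://www.w3.org/2002/07/owl#",
  skos = "http://www.w3.org/2004/02/skos/core#",
  foaf = "http://xmlns.com/foaf/0.1/",
  dcterms = "http://purl.org/dc/terms/",
  sh = "http://www.w3.org/ns/shacl#",
  schema = "https://schema.org/",
  void = "http://rdfs.org/ns/void#",
  up = "http://purl.uniprot.org/core/",
  taxon = "http://purl.uniprot.org/taxonomy/",
  wd = "http://www.wikidata.org/entity/",
  wdt = "http://www.wikidata.org/prop/direct/",
  wikibase = "http://wikiba.se/ontology#",
  bd = "http://www.bigdata.com/rdf#",
  hint = "http://www.bigdata.com/queryHints#",
  obo = "http://purl.obolibrary.org/obo/",
  sio = "http://semanticscience.org/resource/",
  genex = "http://purl.org/genex#",
  orth = "http://purl.org/net/orth#")

#' Construct a prefix registry
#'
#' Common prefixes plus an optional project-specific overlay; overlay entries
#' shadow common entries on label collision.
#'
#' @param common Named character vector (or [prefix_map()]).
#' @param overlay Optional named character vector of project prefixes.
#' @return An object of class `prefix_registry`.
#' @export
prefix_registry <- function(common = DEFAULT_COMMON_PREFIXES, overlay = NULL) {
  common <- prefix_map(common)
  overlay <- if (is.null(overlay)) prefix_map() else prefix_map(overlay)
  structure(list(common = common, overlay = overlay), class = "prefix_registry")
}

registry_lookup <- function(registry, label) {
  if (label %in% names(registry$overlay)) return(registry$overlay[[label]])
  if (label %in% names(registry$common)) return(registry$common[[label]])
  NA_character_
}

#' Read a fixer configuration file
#'
#' Plain key-value lines: `prefix <label>=<namespace>` adds a registry
#' overlay entry, `hint_namespace=<iri>` adds a hint namespace; `#` starts a
#' comment.
#'
#' @param path Config file path.
#' @return list(registry, hint_namespaces).
#' @export
read_fixer_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overlay <- character(0)
  hints <- character(0)
  for (ln in lines) {
    if (grepl("^prefix\\s+", ln)) {
      kv <- sub("^prefix\\s+", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0L) stop("malformed prefix line in config: ", ln)
      overlay[[trimws(substr(kv, 1L, eq - 1L))]] <- trimws(substr(kv, eq + 1L, nchar(kv)))
    } else if (grepl("^hint_namespace\\s*=", ln)) {
      hints <- c(hints, trimws(sub("^hint_namespace\\s*=", "", ln)))
    } else stop("unrecognized config line: ", ln)
  }
  list(registry = prefix_registry(overlay = if (length(overlay)) overlay else NULL),
       hint_namespaces = if (length(hints)) hints else DEFAULT_HINT_NAMESPACES)
}

fix_result <- function(fixed_query, applied_fixes) {
  structure(list(fixed_query = fixed_query, applied_fixes = applied_fixes,
                 changed = length(applied_fixes) > 0L), class = "fix_result")
}

#' @export
print.fix_result <- function(x, ...) {
  cat("<fix_result>", if (x$changed) paste(x$applied_fixes, collapse = ", ") else "no change", "\n")
  invisible(x)
}

# Masks string literals, IRI refs and comments with spaces (preserving
# length) so textual scans cannot be fooled by their content.
mask_opaque_spans <- function(text) {
  masked <- text
  pats <- c('"""(?s:.*?)"""', "'''(?s:.*?)'''", '"(?:[^"\\\\\n]|\\\\.)*"',
            "'(?:[^'\\\\\n]|\\\\.)*'", "<[^<>\"{}|^`\\\\ \t\n]*>", "#[^\n]*")
  for (p in pats) {
    m <- gregexpr(p, masked, perl = TRUE)[[1]]
    if (m[1L] == -1L) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      span <- strrep(" ", lens[k])
      substr(masked, m[k], m[k] + lens[k] - 1L) <- span
    }
  }
  masked
}

fixer_error <- function(code, msg, ...) {
  cond <- simpleError(msg)
  class(cond) <- c(code, "fixer_error", class(cond))
  for (nm in names(list(...))) cond[[nm]] <- list(...)[[nm]]
  stop(cond)
}

#' Add missing PREFIX declarations to a query
#'
#' Every prefix label used in a prefixed name but not declared in the query
#' gets a declaration prepended (in first-use order), resolved from the
#' registry. Operates on a masked token scan, so it works on queries that do
#' not (yet) parse.
#'
#' @param query_text Query text.
#' @param registry A [prefix_registry()].
#' @return A `fix_result` with `PREFIX_ADDED(<label>)` codes.
#' @export
add_missing_prefixes <- function(query_text, registry = prefix_registry()) {
  masked <- mask_opaque_spans(query_text)
  decl_pat <- "(?i)\\bPREFIX[ \t\r\n]+((?:[A-Za-z_][A-Za-z0-9_.-]*)?):"
  m <- gregexpr(decl_pat, masked, perl = TRUE)[[1]]
  declared <- character(0)
  decl_spans <- integer(0)
  if (m[1L] != -1L) {
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      frag <- substr(masked, m[k], m[k] + lens[k] - 1L)
      declared <- c(declared, sub("(?i)^PREFIX[ \t\r\n]+", "", sub(":$", "", frag), perl = TRUE))
      decl_spans <- c(decl_spans, m[k] + lens[k] - 1L)  # position of the ':'
    }
  }
  use_pat <- "(?:^|[ \t\r\n{}(),;.\\[\\]/|^!=<>*+?&-])((?:[A-Za-z_][A-Za-z0-9_.-]*)?):(?![ \t\r\n])"
  um <- gregexpr(use_pat, masked, perl = TRUE)[[1]]
  used <- character(0)
  if (um[1L] != -1L) {
    lens <- attr(um, "match.length")
    starts <- attr(um, "capture.start")[, 1L]
    clens <- attr(um, "capture.length")[, 1L]
    for (k in seq_along(um)) {
      colon_pos <- starts[k] + clens[k]
      if (colon_pos %in% decl_spans) next   # this is the declaration itself
      used <- c(used, substr(masked, starts[k], starts[k] + clens[k] - 1L))
    }
  }
  missing <- setdiff(unique(used), declared)
  if (!length(missing)) return(fix_result(query_text, character(0)))
  unknown <- missing[vapply(missing, function(l) is.na(registry_lookup(registry, l)), logical(1))]
  if (length(unknown))
    fixer_error("fixer_unknown_prefix",
                paste0("prefix label(s) not in the registry: ",
                       paste(paste0("'", unknown, ":'"), collapse = ", ")),
                labels = unknown)
  decls <- vapply(missing, function(l)
    paste0("PREFIX ", l, ": <", registry_lookup(registry, l), ">"), character(1))
  fix_result(paste0(paste(decls, collapse = "\n"), "\n", query_text),
             paste0("PREFIX_ADDED(", missing, ")"))
}

# Finds the matching close brace in masked text, starting at an open brace.
match_brace <- function(masked, open_pos) {
  depth <- 0L
  n <- nchar(masked)
  for (i in open_pos:n) {
    ch <- substr(masked, i, i)
    if (ch == "{") depth <- depth + 1L
    else if (ch == "}") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  stop("unbalanced braces in query")
}

#' Rewrite Blazegraph named subqueries into standard subselects
#'
#' Each `WITH { <subselect> } AS %name` declaration is removed and every
#' `INCLUDE %name` is replaced in place by the braced subselect (multiple
#' INCLUDEs duplicate it).
#'
#' @param query_text Query text.
#' @return A `fix_result` with `NAMED_SUBQUERY_INLINED(<name>)` codes.
#' @export
rewrite_named_subqueries <- function(query_text) {
  text <- query_text
  applied <- character(0)
  defined <- character(0)
  included <- character(0)
  repeat {
    masked <- mask_opaque_spans(text)
    m <- regexpr("(?i)\\bWITH[ \t\r\n]*\\{", masked, perl = TRUE)
    if (m == -1L) break
    open_pos <- m + attr(m, "match.length") - 1L
    close_pos <- match_brace(masked, open_pos)
    tail_pat <- "^[ \t\r\n]*AS[ \t\r\n]*%([A-Za-z_][A-Za-z0-9_]*)"
    tail_m <- regexpr(tail_pat, substr(masked, close_pos + 1L, nchar(masked)), perl = TRUE)
    if (tail_m != 1L)
      fixer_error("fixer_named_subquery_error", "WITH block is not followed by AS %name")
    tail_len <- attr(tail_m, "match.length")
    name <- sub(tail_pat, "\\1",
                substr(text, close_pos + 1L, close_pos + tail_len), perl = TRUE)
    sub_text <- substr(text, open_pos + 1L, close_pos - 1L)
    # drop the declaration
    text <- paste0(substr(text, 1L, m - 1L), substr(text, close_pos + tail_len + 1L, nchar(text)))
    defined[[name]] <- sub_text
    applied <- c(applied, paste0("NAMED_SUBQUERY_INLINED(", name, ")"))
  }
  # replace INCLUDEs
  repeat {
    masked <- mask_opaque_spans(text)
    m <- regexpr("(?i)\\bINCLUDE[ \t\r\n]*%([A-Za-z_][A-Za-z0-9_]*)", masked, perl = TRUE)
    if (m == -1L) break
    len <- attr(m, "match.length")
    name <- sub("(?i)^INCLUDE[ \t\r\n]*%", "", substr(text, m, m + len - 1L), perl = TRUE)
    if (!name %in% names(defined))
      fixer_error("fixer_undefined_subquery",
                  paste0("INCLUDE of undefined named subquery %", name))
    included <- c(included, name)
    text <- paste0(substr(text, 1L, m - 1L), "{", defined[[name]], "}",
                   substr(text, m + len, nchar(text)))
  }
  unused <- setdiff(names(defined), included)
  if (length(unused))
    warning("named subquery declared but never included, dropped: ",
            paste(paste0("%", unused), collapse = ", "))
  fix_result(text, applied)
}

#' Strip vendor query-hint ("magic") triple patterns
#'
#' Removes every triple pattern whose subject or predicate IRI starts with a
#' configured hint namespace; everything else in the query text, including
#' comments outside removed statements, is preserved verbatim.
#'
#' @param query_text Query text (must parse; run prefix fixing first).
#' @param hint_namespaces Character vector of IRI prefixes.
#' @return A `fix_result` with a `HINT_REMOVED(<count>)` code.
#' @export
strip_query_hints <- function(query_text, hint_namespaces = DEFAULT_HINT_NAMESPACES) {
  q <- parse_sparql(query_text)
  is_hint_iri <- function(iri) !is.na(iri) && any(startsWith(iri, hint_namespaces))
  removals <- list()   # list of c(start, end)
  n_removed <- 0L
  for (stmt in q$statements) {
    subj_hint <- is_hint_iri(stmt$subject)
    po_hint <- vapply(stmt$pos, function(po) is_hint_iri(po$pred), logical(1))
    if (subj_hint || all(po_hint)) {
      removals[[length(removals) + 1L]] <- stmt$span
      n_removed <- n_removed + sum(vapply(stmt$pos, function(po) po$n_tp, integer(1)))
    } else if (any(po_hint)) {
      # rebuild the statement without its hint predicate-object groups
      kept <- stmt$pos[!po_hint]
      n_removed <- n_removed + sum(vapply(stmt$pos[po_hint], function(po) po$n_tp, integer(1)))
      subj_txt <- trimws(substr(query_text, stmt$span[1L],
                                stmt$pos[[1L]]$span[1L] - 1L))
      po_txt <- vapply(kept, function(po)
        substr(query_text, po$span[1L], po$span[2L]), character(1))
      replacement <- paste0(subj_txt, " ", paste(po_txt, collapse = " ;\n    "), " .")
      removals[[length(removals) + 1L]] <- c(stmt$span[1L], stmt$span[2L], NA_integer_)
      attr(removals[[length(removals)]], "replacement") <- replacement
    }
  }
  if (!length(removals)) return(fix_result(query_text, character(0)))
  # apply removals back-to-front so earlier offsets stay valid
  ord <- order(vapply(removals, `[`, numeric(1), 1L), decreasing = TRUE)
  text <- query_text
  for (k in ord) {
    span <- removals[[k]]
    repl <- attr(span, "replacement")
    if (is.null(repl)) repl <- ""
    text <- paste0(substr(text, 1L, span[1L] - 1L), repl,
                   substr(text, span[2L] + 1L, nchar(text)))
  }
  # collapse lines left fully blank by a removal
  text <- gsub("\n[ \t]*\n", "\n", text)
  check <- tryCatch(parse_sparql(text), error = function(e) e)
  if (inherits(check, "error"))
    fixer_error("fixer_strip_error",
                paste0("query no longer parses after hint removal: ", conditionMessage(check)))
  if (!is.null(check$where) && !length(check$where$elts))
    fixer_error("fixer_all_hints", "removing hint patterns left an empty WHERE pattern")
  fix_result(text, paste0("HINT_REMOVED(", n_removed, ")"))
}

#' Fix a query to be fully SPARQL 1.1 compliant
#'
#' Pipeline: missing prefixes, then named-subquery rewriting, then hint
#' stripping. The result is guaranteed to parse under the strict grammar.
#'
#' @param query_text Query text.
#' @param registry A [prefix_registry()].
#' @param hint_namespaces Character vector of hint IRI prefixes.
#' @return A `fix_result` with the concatenated fix codes in pipeline order.
#' @export
fix_query <- function(query_text, registry = prefix_registry(),
                      hint_namespaces = DEFAULT_HINT_NAMESPACES) {
  stage <- function(name, f, text) {
    tryCatch(f(text), fixer_error = function(e) {
      e$message <- paste0("[", name, "] ", conditionMessage(e))
      stop(e)
    })
  }
  r1 <- stage("prefixes", function(t) add_missing_prefixes(t, registry), query_text)
  r2 <- stage("named-subqueries", rewrite_named_subqueries, r1$fixed_query)
  r3 <- stage("hints", function(t) strip_query_hints(t, hint_namespaces), r2$fixed_query)
  applied <- c(r1$applied_fixes, r2$applied_fixes, r3$applied_fixes)
  final <- r3$fixed_query
  check <- tryCatch(parse_sparql(final), error = function(e) e)
  if (inherits(check, "error"))
    fixer_error("fixer_parse_error",
                paste0("fixed query does not parse: ", conditionMessage(check)))
  fix_result(final, applied)
}
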