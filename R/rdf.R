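# RDF terms, graphs, and Turtle-family reading/writing.
#
# Terms are encoded as single character strings in an N-Triples-like form:
#   IRI      "<http://example.org/x>"
#   bnode    "_:b1"
#   literal  "\"text\"", "\"text\"@en", "\"1\"^^<http://www.w3.org/2001/XMLSchema#integer>"
# A graph is a data.frame with columns s, p, o, g (g is NA for the default graph).

#' Construct an IRI term
#'
#' @param iri Character vector of absolute IRIs (without angle brackets).
#' @return Encoded IRI term(s).
#' @export
rdf_iri <- function(iri) paste0("<", iri, ">")

#' Construct a blank node term
#'
#' @param label Blank node label(s) without the `_:` prefix.
#' @return Encoded blank node term(s).
#' @export
rdf_bnode <- function(label) paste0("_:", label)

#' Construct a literal term
#'
#' @param value Character vector of lexical values.
#' @param lang Optional BCP-47 language tag.
#' @param datatype Optional datatype IRI (without angle brackets).
#' @return Encoded literal term(s).
#' @export
rdf_literal <- function(value, lang = NULL, datatype = NULL) {
  if (!is.null(lang) && !is.null(datatype)) stop("a literal cannot have both a language tag and a datatype")
  enc <- paste0('"', escape_string(value), '"')
  if (!is.null(lang) && nzchar(lang)) enc <- paste0(enc, "@", lang)
  else if (!is.null(datatype) && nzchar(datatype) && datatype != paste0(XSD, "string"))
    enc <- paste0(enc, "^^<", datatype, ">")
  enc
}

escape_string <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_string <- function(x) {
  if (!grepl("\\", x, fixed = TRUE)) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\\" && i < n) {
      nx <- chars[i + 1L]
      rep <- switch(nx,
        n = "\n", r = "\r", t = "\t", b = "\b", f = "\f",
        '"' = '"', "'" = "'", "\\" = "\\",
        u = NA_character_, U = NA_character_, NULL)
      if (nx %in% c("u", "U")) {
        k <- if (nx == "u") 4L else 8L
        hex <- paste(chars[(i + 2L):(i + 1L + k)], collapse = "")
        out <- c(out, intToUtf8(strtoi(hex, 16L)))
        i <- i + 2L + k
        next
      } else if (!is.null(rep)) {
        out <- c(out, rep)
        i <- i + 2L
        next
      }
    }
    out <- c(out, ch)
    i <- i + 1L
  }
  paste(out, collapse = "")
}

#' Term type of an encoded RDF term
#'
#' @param term Encoded term(s).
#' @return "iri", "bnode", "literal" or "var".
#' @export
term_type <- function(term) {
  first <- substr(term, 1L, 1L)
  ifelse(first == "<", "iri",
    ifelse(first == "_", "bnode",
      ifelse(first == '"', "literal",
        ifelse(first %in% c("?", "$"), "var", NA_character_))))
}

#' @rdname term_type
#' @export
iri_value <- function(term) sub("^<(.*)>$", "\\1", term)

# Splits an encoded literal into value / lang / datatype.
literal_parts <- function(term) {
  m <- regmatches(term, regexec('^"((?s:.*))"(?:@([A-Za-z0-9-]+)|\\^\\^<([^>]*)>)?$', term, perl = TRUE))[[1]]
  if (length(m) == 0L) stop("not a literal term: ", term)
  list(value = unescape_string(m[2]),
       lang = if (nzchar(m[3])) m[3] else NA_character_,
       datatype = if (nzchar(m[4])) m[4] else NA_character_)
}

#' @rdname term_type
#' @export
literal_value <- function(term) vapply(term, function(t) literal_parts(t)$value, character(1), USE.NAMES = FALSE)

#' @rdname term_type
#' @export
literal_lang <- function(term) vapply(term, function(t) literal_parts(t)$lang, character(1), USE.NAMES = FALSE)

#' @rdname term_type
#' @export
literal_datatype <- function(term) {
  vapply(term, function(t) {
    p <- literal_parts(t)
    if (!is.na(p$datatype)) p$datatype
    else if (!is.na(p$lang)) paste0(RDF_NS, "langString")
    else paste0(XSD, "string")
  }, character(1), USE.NAMES = FALSE)
}

#' Create an RDF graph
#'
#' @param s,p,o Encoded subject, predicate and object terms.
#' @param g Graph name terms (NA for the default graph).
#' @return An object of class `rdf_graph` (a data.frame with columns s, p, o, g).
#' @export
rdf_graph <- function(s = character(0), p = character(0), o = character(0), g = NA_character_) {
  df <- data.frame(s = as.character(s), p = as.character(p), o = as.character(o),
                   g = if (length(s)) as.character(g) else character(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("rdf_graph", "data.frame")
  df
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat("RDF graph:", nrow(x), "triple(s)")
  ngs <- unique(x$g[!is.na(x$g)])
  if (length(ngs)) cat(",", length(ngs), "named graph(s)")
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

rbind_graphs <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (!length(parts)) return(rdf_graph())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("rdf_graph", "data.frame")
  rownames(out) <- NULL
  out
}

# Triples of `graph` in named graph `g` (NA = default graph).
graph_slice <- function(graph, g) {
  keep <- if (is.na(g)) is.na(graph$g) else !is.na(graph$g) & graph$g == g
  out <- graph[keep, , drop = FALSE]
  class(out) <- c("rdf_graph", "data.frame")
  out
}

# objects for (s, p); subjects for (p, o)
graph_objects <- function(graph, s, p) graph$o[graph$s == s & graph$p == p]
graph_subjects <- function(graph, p, o) graph$s[graph$p == p & graph$o == o]

## ---------------------------------------------------------------------------
## Tokenizer shared by the Turtle-family reader and the SPARQL parser

TOKEN_PATTERNS <- list(
  c("WS", "^[ \t\r\n ]+"),
  c("COMMENT", "^#[^\n]*"),
  c("IRIREF", "^<[^<>\"{}|^`\\\\ \t\n]*>"),
  c("STRING_LONG", "^\"\"\""),          # handled procedurally
  c("STRING_LONG1", "^'''"),
  c("STRING", "^\"(?:[^\"\\\\\n]|\\\\.)*\""),
  c("STRING1", "^'(?:[^'\\\\\n]|\\\\.)*'"),
  c("VAR", "^[?$][A-Za-z0-9_]+"),
  c("BNODE", "^_:[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?"),
  c("LANGTAG", "^@[A-Za-z]+(?:-[A-Za-z0-9]+)*"),
  c("PNAME_LN", "^(?:[A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_%](?:[A-Za-z0-9_.:%-]*[A-Za-z0-9_%-])?"),
  c("PNAME_NS", "^(?:[A-Za-z_][A-Za-z0-9_.-]*)?:"),
  c("DOUBLE", "^[+-]?(?:[0-9]+\\.[0-9]*|\\.?[0-9]+)[eE][+-]?[0-9]+"),
  c("DECIMAL", "^[+-]?[0-9]*\\.[0-9]+"),
  c("INTEGER", "^[+-]?[0-9]+"),
  c("IDENT", "^[A-Za-z_][A-Za-z0-9_]*"),
  c("OP2", "^(?:\\^\\^|&&|\\|\\||!=|<=|>=)"),
  c("PUNCT", "^[;,.\\[\\](){}*/|^!=<>?$+-]")
)

# Finds the end of a long string starting at `pos` (pointing at the opening
# triple quote). Returns the index of the last quote character.
long_string_end <- function(text, pos, quote) {
  q3 <- strrep(quote, 3L)
  i <- pos + 3L
  n <- nchar(text)
  while (i <= n - 2L) {
    hit <- regexpr(q3, substr(text, i, n), fixed = TRUE)
    if (hit < 0L) break
    cand <- i + hit - 1L
    # count preceding backslashes
    j <- cand - 1L
    nb <- 0L
    while (j >= 1L && substr(text, j, j) == "\\") { nb <- nb + 1L; j <- j - 1L }
    if (nb %% 2L == 0L) {
      # extend over any extra quotes (content quotes precede the terminator)
      while (cand + 3L <= n && substr(text, cand + 3L, cand + 3L) == quote) cand <- cand + 1L
      return(cand + 2L)
    }
    i <- cand + 1L
  }
  stop("unterminated long string starting at character ", pos)
}

# Tokenizes Turtle/SPARQL text. Returns a data.frame with columns
# type, text, start, end (1-based character offsets, inclusive).
tokenize_rdf <- function(text) {
  n <- nchar(text)
  types <- character(0); texts <- character(0); starts <- integer(0); ends <- integer(0)
  pos <- 1L
  while (pos <= n) {
    rest <- substr(text, pos, n)
    matched <- FALSE
    for (pat in TOKEN_PATTERNS) {
      m <- regexpr(pat[2], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        type <- pat[1]
        if (type %in% c("STRING_LONG", "STRING_LONG1")) {
          q <- if (type == "STRING_LONG") '"' else "'"
          endpos <- long_string_end(text, pos, q)
          len <- endpos - pos + 1L
          type <- "STRING_LONG"
        }
        if (!type %in% c("WS", "COMMENT")) {
          types <- c(types, type)
          texts <- c(texts, substr(text, pos, pos + len - 1L))
          starts <- c(starts, pos)
          ends <- c(ends, pos + len - 1L)
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      line <- 1L + lengths(regmatches(substr(text, 1L, pos), gregexpr("\n", substr(text, 1L, pos), fixed = TRUE)))
      stop(sprintf("lexical error at line %d near '%s'", line, substr(text, pos, min(n, pos + 20L))))
    }
  }
  data.frame(type = types, text = texts, start = starts, end = ends, stringsAsFactors = FALSE)
}

token_line <- function(text, offset) {
  1L + lengths(regmatches(substr(text, 1L, offset), gregexpr("\n", substr(text, 1L, offset), fixed = TRUE)))
}

# Decodes a string token (short or long, either quote) into its raw value.
string_token_value <- function(tok) {
  txt <- tok
  if (startsWith(txt, '"""') || startsWith(txt, "'''")) {
    inner <- substr(txt, 4L, nchar(txt) - 3L)
  } else {
    inner <- substr(txt, 2L, nchar(txt) - 1L)
  }
  unescape_string(inner)
}

number_token_literal <- function(type, text) {
  dt <- switch(type, INTEGER = "integer", DECIMAL = "decimal", DOUBLE = "double")
  paste0('"', text, '"^^<', XSD, dt, ">")
}

## ---------------------------------------------------------------------------
## Turtle / TriG / N-Triples / N-Quads reader

#' Parse RDF text in a Turtle-family syntax
#'
#' Supports the Turtle constructs used by the SPARQL-example representation
#' (prefix/base directives, predicate-object and object lists, blank node
#' property lists, typed/tagged literals incl. triple-quoted strings) plus
#' TriG named-graph blocks and line-based N-Triples/N-Quads.
#'
#' @param text Turtle/TriG/N-Triples/N-Quads source text.
#' @param base Optional base IRI used to resolve relative IRIs.
#' @param format One of "turtle", "trig", "ntriples", "nquads" ("turtle"
#'   accepts TriG graph blocks as well; N-Triples/N-Quads are a subset).
#' @param bnode_prefix Internal prefix used to keep blank node labels from
#'   distinct documents disjoint.
#' @return An [rdf_graph()].
#' @export
parse_rdf <- function(text, base = NULL, format = "turtle", bnode_prefix = "b") {
  toks <- tokenize_rdf(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  st$n <- nrow(toks)
  st$prefixes <- character(0)      # named: label -> namespace
  st$base <- base
  st$text <- text
  st$bcount <- 0L
  st$bprefix <- bnode_prefix
  st$s <- character(0); st$p <- character(0); st$o <- character(0); st$g <- character(0)
  st$current_graph <- NA_character_

  while (st$i <= st$n) parse_ttl_statement(st)
  g <- rdf_graph(st$s, st$p, st$o, st$g)
  attr(g, "prefixes") <- st$prefixes
  g
}

peek <- function(st, k = 0L) if (st$i + k <= st$n) st$toks[st$i + k, ] else NULL
advance <- function(st) { tok <- st$toks[st$i, ]; st$i <- st$i + 1L; tok }

ttl_error <- function(st, msg) {
  off <- if (st$i <= st$n) st$toks$start[st$i] else nchar(st$text)
  stop(sprintf("Turtle parse error at line %d: %s", token_line(st$text, off), msg), call. = FALSE)
}

expect_punct <- function(st, ch) {
  tok <- peek(st)
  if (is.null(tok) || tok$text != ch) ttl_error(st, paste0("expected '", ch, "'"))
  advance(st)
}

fresh_bnode <- function(st) {
  st$bcount <- st$bcount + 1L
  rdf_bnode(paste0(st$bprefix, "_gen", st$bcount))
}

emit_triple <- function(st, s, p, o) {
  st$s <- c(st$s, s); st$p <- c(st$p, p); st$o <- c(st$o, o)
  st$g <- c(st$g, st$current_graph)
}

resolve_pname <- function(st, txt) {
  idx <- regexpr(":", txt, fixed = TRUE)
  label <- substr(txt, 1L, idx - 1L)
  local <- substr(txt, idx + 1L, nchar(txt))
  if (!label %in% names(st$prefixes)) ttl_error(st, paste0("undeclared prefix '", label, ":'"))
  ns <- st$prefixes[[label]]
  rdf_iri(paste0(ns, local))
}

resolve_iriref <- function(st, txt) {
  iri <- substr(txt, 2L, nchar(txt) - 1L)
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri)) {
    if (is.null(st$base)) return(rdf_iri(iri))
    iri <- paste0(sub("[^/]*$", "", st$base), iri)
  }
  rdf_iri(iri)
}

parse_ttl_statement <- function(st) {
  tok <- peek(st)
  up <- toupper(tok$text)
  if (tok$type == "LANGTAG" && tok$text %in% c("@prefix", "@base")) {
    directive <- tok$text
    advance(st)
    if (directive == "@prefix") {
      ns_tok <- advance(st)
      if (!ns_tok$type %in% c("PNAME_NS", "PNAME_LN")) ttl_error(st, "expected prefix label")
      label <- sub(":.*$", "", sub(":$", "", ns_tok$text))
      iri_tok <- advance(st)
      if (iri_tok$type != "IRIREF") ttl_error(st, "expected namespace IRI")
      st$prefixes[[label]] <- iri_value(resolve_iriref(st, iri_tok$text))
    } else {
      iri_tok <- advance(st)
      st$base <- iri_value(resolve_iriref(st, iri_tok$text))
    }
    expect_punct(st, ".")
    return(invisible())
  }
  if (tok$type == "IDENT" && up %in% c("PREFIX", "BASE")) {
    advance(st)
    if (up == "PREFIX") {
      ns_tok <- advance(st)
      if (!ns_tok$type %in% c("PNAME_NS", "PNAME_LN")) ttl_error(st, "expected prefix label")
      label <- sub(":$", "", ns_tok$text)
      iri_tok <- advance(st)
      if (iri_tok$type != "IRIREF") ttl_error(st, "expected namespace IRI")
      st$prefixes[[label]] <- iri_value(resolve_iriref(st, iri_tok$text))
    } else {
      iri_tok <- advance(st)
      st$base <- iri_value(resolve_iriref(st, iri_tok$text))
    }
    return(invisible())
  }
  if (tok$type == "IDENT" && up == "GRAPH") {   # TriG
    advance(st)
    name_tok <- advance(st)
    gname <- ttl_term_from_token(st, name_tok)
    parse_trig_block(st, gname)
    return(invisible())
  }
  # TriG block without GRAPH keyword: <g> { ... }
  if (tok$type %in% c("IRIREF", "PNAME_LN", "PNAME_NS", "BNODE")) {
    nxt <- peek(st, 1L)
    if (!is.null(nxt) && nxt$text == "{") {
      name_tok <- advance(st)
      gname <- ttl_term_from_token(st, name_tok)
      parse_trig_block(st, gname)
      return(invisible())
    }
  }
  if (tok$text == "{") {  # default-graph block
    parse_trig_block(st, NA_character_)
    return(invisible())
  }
  parse_ttl_triples(st)
  # statement terminator: '.' (optional before '}' in TriG blocks)
  tok <- peek(st)
  if (!is.null(tok) && tok$text == ".") advance(st)
  else if (is.null(tok) || tok$text != "}") ttl_error(st, "expected '.'")
}

parse_trig_block <- function(st, gname) {
  expect_punct(st, "{")
  prev <- st$current_graph
  st$current_graph <- if (is.na(gname)) NA_character_ else iri_value_or_self(gname)
  while (!is.null(peek(st)) && peek(st)$text != "}") {
    parse_ttl_triples(st)
    tok <- peek(st)
    if (!is.null(tok) && tok$text == ".") advance(st)
  }
  expect_punct(st, "}")
  st$current_graph <- prev
}

iri_value_or_self <- function(term) if (term_type(term) == "iri") iri_value(term) else term

ttl_term_from_token <- function(st, tok) {
  switch(tok$type,
    IRIREF = resolve_iriref(st, tok$text),
    PNAME_LN = resolve_pname(st, tok$text),
    PNAME_NS = resolve_pname(st, tok$text),
    BNODE = rdf_bnode(paste0(st$bprefix, "_", substr(tok$text, 3L, nchar(tok$text)))),
    ttl_error(st, paste0("unexpected token '", tok$text, "'")))
}

parse_ttl_subject <- function(st) {
  tok <- peek(st)
  if (tok$text == "[") {
    advance(st)
    node <- fresh_bnode(st)
    if (peek(st)$text != "]") parse_ttl_polist(st, node)
    expect_punct(st, "]")
    return(node)
  }
  advance(st)
  ttl_term_from_token(st, tok)
}

parse_ttl_triples <- function(st) {
  subj <- parse_ttl_subject(st)
  parse_ttl_polist(st, subj)
}

parse_ttl_polist <- function(st, subj) {
  repeat {
    tok <- peek(st)
    if (is.null(tok)) ttl_error(st, "unexpected end of input in predicate-object list")
    pred <- if (tok$type == "IDENT" && tok$text == "a") { advance(st); rdf_iri(paste0(RDF_NS, "type")) }
            else { advance(st); ttl_term_from_token(st, tok) }
    repeat {
      obj <- parse_ttl_object(st)
      emit_triple(st, subj, pred, obj)
      if (!is.null(peek(st)) && peek(st)$text == ",") advance(st) else break
    }
    if (!is.null(peek(st)) && peek(st)$text == ";") {
      advance(st)
      # tolerate trailing semicolons
      while (!is.null(peek(st)) && peek(st)$text == ";") advance(st)
      if (is.null(peek(st)) || peek(st)$text %in% c(".", "]", "}")) break
    } else break
  }
}

parse_ttl_object <- function(st) {
  tok <- peek(st)
  if (is.null(tok)) ttl_error(st, "unexpected end of input, expected object")
  if (tok$text == "[") {
    advance(st)
    node <- fresh_bnode(st)
    if (peek(st)$text != "]") parse_ttl_polist(st, node)
    expect_punct(st, "]")
    return(node)
  }
  if (tok$type %in% c("STRING", "STRING1", "STRING_LONG")) {
    advance(st)
    value <- string_token_value(tok$text)
    nxt <- peek(st)
    if (!is.null(nxt) && nxt$type == "LANGTAG") {
      advance(st)
      return(rdf_literal(value, lang = substr(nxt$text, 2L, nchar(nxt$text))))
    }
    if (!is.null(nxt) && nxt$text == "^^") {
      advance(st)
      dt_tok <- advance(st)
      return(rdf_literal(value, datatype = iri_value(ttl_term_from_token(st, dt_tok))))
    }
    return(rdf_literal(value))
  }
  if (tok$type %in% c("INTEGER", "DECIMAL", "DOUBLE")) {
    advance(st)
    return(number_token_literal(tok$type, tok$text))
  }
  if (tok$type == "IDENT" && tok$text %in% c("true", "false")) {
    advance(st)
    return(paste0('"', tok$text, '"^^<', XSD, "boolean>"))
  }
  advance(st)
  ttl_term_from_token(st, tok)
}

## ---------------------------------------------------------------------------
## Writer

format_term_ttl <- function(term, prefixes = character(0)) {
  tt <- term_type(term)
  if (tt == "iri") {
    cur <- compact_iri(iri_value(term), prefixes)
    if (!is.na(cur)) return(cur)
    return(term)
  }
  term  # bnodes and literals already in valid Turtle form
}

#' Compact an IRI to a CURIE using a prefix map
#'
#' @param iri Absolute IRI (no angle brackets).
#' @param prefixes Named character vector label -> namespace.
#' @return The CURIE, or NA if no namespace matches or the local part is not a
#'   valid prefixed-name local name.
#' @export
compact_iri <- function(iri, prefixes) {
  if (!length(prefixes)) return(NA_character_)
  hits <- prefixes[startsWith(iri, prefixes) & nzchar(prefixes)]
  if (!length(hits)) return(NA_character_)
  ns <- hits[which.max(nchar(hits))]
  local <- substr(iri, nchar(ns) + 1L, nchar(iri))
  if (!grepl("^(?:[A-Za-z0-9_](?:[A-Za-z0-9_.-]*[A-Za-z0-9_-])?)?$", local)) return(NA_character_)
  paste0(names(ns), ":", local)
}

#' Serialize an RDF graph as Turtle (or TriG when named graphs are present)
#'
#' @param graph An [rdf_graph()].
#' @param prefixes Named character vector label -> namespace used both for the
#'   `@prefix` header and to compact IRIs.
#' @return A single Turtle/TriG string.
#' @export
serialize_rdf <- function(graph, prefixes = character(0)) {
  header <- if (length(prefixes))
    paste0(vapply(seq_along(prefixes), function(i)
      sprintf("@prefix %s: <%s> .", names(prefixes)[i], prefixes[[i]]), character(1)),
      collapse = "\n")
  else ""
  body <- function(slice, indent = "") {
    if (!nrow(slice)) return(character(0))
    out <- character(0)
    for (subj in unique(slice$s)) {
      rows <- slice[slice$s == subj, , drop = FALSE]
      lines <- character(0)
      for (pred in unique(rows$p)) {
        objs <- rows$o[rows$p == pred]
        pd <- if (pred == rdf_iri(paste0(RDF_NS, "type"))) "a" else format_term_ttl(pred, prefixes)
        od <- paste(vapply(objs, format_term_ttl, character(1), prefixes = prefixes), collapse = ", ")
        lines <- c(lines, paste0(indent, "    ", pd, " ", od))
      }
      out <- c(out, paste0(indent, format_term_ttl(subj, prefixes), "\n",
                           paste(lines, collapse = " ;\n"), " ."))
    }
    out
  }
  parts <- character(0)
  def <- graph[is.na(graph$g), , drop = FALSE]
  parts <- c(parts, body(def))
  for (gname in unique(graph$g[!is.na(graph$g)])) {
    slice <- graph[!is.na(graph$g) & graph$g == gname, , drop = FALSE]
    parts <- c(parts, paste0("GRAPH <", gname, "> {\n",
                             paste(body(slice, "  "), collapse = "\n\n"), "\n}"))
  }
  paste0(if (nzchar(header)) paste0(header, "\n\n") else "", paste(parts, collapse = "\n\n"), "\n")
}

## ---------------------------------------------------------------------------
## Graph isomorphism (blank-node bijection; exact on ground triples)

triple_keys <- function(graph) paste(graph$s, graph$p, graph$o, ifelse(is.na(graph$g), "", graph$g))

#' Test whether two RDF graphs are isomorphic
#'
#' Ground triples must match as multisets; blank nodes are matched by trying
#' label bijections (graphs in this package carry few blank nodes).
#'
#' @param g1,g2 [rdf_graph()] objects.
#' @return TRUE or FALSE.
#' @export
graphs_isomorphic <- function(g1, g2) {
  if (nrow(g1) != nrow(g2)) return(FALSE)
  bn <- function(g) unique(c(g$s[term_type(g$s) == "bnode"], g$o[term_type(g$o) == "bnode"]))
  b1 <- bn(g1); b2 <- bn(g2)
  if (length(b1) != length(b2)) return(FALSE)
  ground <- function(g, bset) {
    keep <- !(g$s %in% bset) & !(g$o %in% bset)
    sort(triple_keys(g[keep, , drop = FALSE]))
  }
  if (!identical(ground(g1, b1), ground(g2, b2))) return(FALSE)
  if (!length(b1)) return(TRUE)
  # partition blank nodes by iteratively refined neighborhood signatures, then
  # only try bijections within matching signature classes
  sig1 <- bnode_signatures(g1, b1)
  sig2 <- bnode_signatures(g2, b2)
  if (!identical(sort(unname(sig1)), sort(unname(sig2)))) return(FALSE)
  classes <- unique(sig1)
  c1 <- lapply(classes, function(cl) b1[sig1 == cl])
  c2 <- lapply(classes, function(cl) b2[sig2 == cl])
  if (prod(factorial(lengths(c1))) > 5000) stop("graphs_isomorphic: blank node structure too ambiguous")
  target <- sort(triple_keys(g2))
  try_class <- function(k, map) {
    if (k > length(classes)) {
      s <- ifelse(g1$s %in% b1, unname(map[g1$s]), g1$s)
      o <- ifelse(g1$o %in% b1, unname(map[g1$o]), g1$o)
      gm <- g1; gm$s <- s; gm$o <- o
      return(identical(sort(triple_keys(gm)), target))
    }
    for (pm in permutations_of(seq_along(c2[[k]]))) {
      map[c1[[k]]] <- c2[[k]][pm]
      if (try_class(k + 1L, map)) return(TRUE)
    }
    FALSE
  }
  try_class(1L, stats::setNames(character(length(b1)), b1))
}

# Iterative refinement: each blank node's signature summarizes its incident
# triples, with neighboring blank nodes replaced by their previous-round
# signature.
bnode_signatures <- function(g, bset) {
  colors <- stats::setNames(rep("0", length(bset)), bset)
  for (iter in 1:3) {
    colors <- vapply(bset, function(b) {
      enc <- function(x) ifelse(x %in% bset, paste0("~", colors[x]), x)
      out_rows <- which(g$s == b)
      in_rows <- which(g$o == b)
      feats <- c(paste0(">", g$p[out_rows], " ", enc(g$o[out_rows])),
                 paste0("<", g$p[in_rows], " ", enc(g$s[in_rows])))
      paste(sort(feats), collapse = ";")
    }, character(1))
    colors <- stats::setNames(as.character(match(colors, sort(unique(colors)))), bset)
  }
  colors
}

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
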