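# The question--query example data model and its Turtle representation.
#
# One example per .ttl file: a sh:SPARQLExecutable subject carrying the query
# (sh:select / sh:ask / sh:construct / sh:update / spex:describe), the natural
# language question(s) as language-tagged rdfs:comment literals, the target
# endpoint(s) as schema:target, optional schema:keywords tags, an optional
# spex:federatesWith federation declaration and an optional sh:prefixes node.

QUERY_KIND_PROPERTY <- c(
  select = paste0(SH_NS, "select"),
  ask = paste0(SH_NS, "ask"),
  construct = paste0(SH_NS, "construct"),
  update = paste0(SH_NS, "update"),
  describe = paste0(SPEX_NS, "describe"))

QUERY_KIND_SUBTYPE <- c(
  select = paste0(SH_NS, "SPARQLSelectExecutable"),
  ask = paste0(SH_NS, "SPARQLAskExecutable"),
  construct = paste0(SH_NS, "SPARQLConstructExecutable"),
  update = paste0(SH_NS, "SPARQLUpdateExecutable"))

SH_EXECUTABLE <- paste0(SH_NS, "SPARQLExecutable")

is_absolute_iri <- function(x) grepl("^[A-Za-z][A-Za-z0-9+.-]*://?[^ ]+$", x) | grepl("^urn:", x)

#' Construct a prefix map
#'
#' An ordered mapping from prefix labels to absolute namespace IRIs. Labels
#' must satisfy the SPARQL prefix-label grammar (the empty label is the
#' default prefix) and be unique.
#'
#' @param ... Named namespace IRIs (`up = "http://purl.uniprot.org/core/"`),
#'   or a single named character vector.
#' @return A named character vector of class `prefix_map`.
#' @export
prefix_map <- function(...) {
  args <- list(...)
  entries <- if (length(args) == 1L && is.null(names(args)) && is.character(args[[1L]])) args[[1L]]
             else unlist(args)
  if (is.null(entries)) entries <- character(0)
  labels <- names(entries)
  if (length(entries) && is.null(labels)) stop("prefix entries must be named by their labels")
  if (is.null(labels)) labels <- character(0)
  bad <- labels[!grepl("^(?:[A-Za-z_][A-Za-z0-9_.-]*)?$", labels)]
  if (length(bad)) stop("invalid prefix label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(labels)) stop("duplicate prefix label(s): ",
                                  paste(unique(labels[duplicated(labels)]), collapse = ", "))
  not_iri <- entries[!is_absolute_iri(entries)]
  if (length(not_iri)) stop("namespace is not an absolute IRI: ", paste(not_iri, collapse = ", "))
  structure(entries, class = "prefix_map")
}

#' @export
print.prefix_map <- function(x, ...) {
  cat("<prefix_map> with", length(x), "entries\n")
  for (i in seq_along(x)) cat(" ", names(x)[i], "-> ", x[[i]], "\n")
  invisible(x)
}

#' Construct an example document
#'
#' @param id Absolute IRI identifying the example (NA when the source file
#'   used a blank node; validation flags this).
#' @param kind One of "select", "ask", "construct", "update", "describe".
#' @param query SPARQL query text.
#' @param comments data.frame with columns `text` and `lang` (NA = no tag),
#'   or a character vector (languages taken from names).
#' @param targets Character vector of target endpoint IRIs.
#' @param keywords Character vector of keyword tags.
#' @param federates_with Character vector of remote endpoint IRIs the query
#'   is declared to federate with.
#' @param prefixes A [prefix_map()] reported via `sh:prefixes`.
#' @param declared_types Character vector of declared SHACL type IRIs
#'   (retained for consistency checking).
#' @param has_prefix_node Whether the source carried an `sh:prefixes` node.
#' @return An object of class `example_document`.
#' @export
example_document <- function(id, kind, query, comments = NULL, targets = character(0),
                             keywords = character(0), federates_with = character(0),
                             prefixes = prefix_map(), declared_types = NULL,
                             has_prefix_node = length(prefixes) > 0L) {
  if (is.null(comments)) comments <- data.frame(text = character(0), lang = character(0),
                                                stringsAsFactors = FALSE)
  if (is.character(comments)) {
    langs <- if (is.null(names(comments))) rep(NA_character_, length(comments)) else names(comments)
    comments <- data.frame(text = unname(comments), lang = ifelse(nzchar(langs), langs, NA_character_),
                           stringsAsFactors = FALSE)
  }
  if (!kind %in% names(QUERY_KIND_PROPERTY)) stop("unknown query kind: ", kind)
  if (is.null(declared_types)) {
    declared_types <- SH_EXECUTABLE
    if (kind != "describe") declared_types <- c(QUERY_KIND_SUBTYPE[[kind]], declared_types)
  }
  structure(list(id = id, kind = kind, query = query, comments = comments,
                 targets = targets, keywords = keywords, federates_with = federates_with,
                 prefixes = prefixes, declared_types = declared_types,
                 has_prefix_node = has_prefix_node),
            class = "example_document")
}

#' @export
print.example_document <- function(x, ...) {
  cat("<example_document>", if (is.na(x$id)) "(blank-node id)" else x$id, "\n")
  cat("  kind:    ", x$kind, "\n")
  if (nrow(x$comments)) cat("  question:", x$comments$text[1L],
    if (!is.na(x$comments$lang[1L])) paste0("(@", x$comments$lang[1L], ")"), "\n")
  cat("  targets: ", paste(x$targets, collapse = ", "), "\n")
  if (length(x$keywords)) cat("  keywords:", paste(x$keywords, collapse = ", "), "\n")
  if (length(x$federates_with)) cat("  federates with:", paste(x$federates_with, collapse = ", "), "\n")
  invisible(x)
}

example_error <- function(code, msg) {
  cond <- simpleError(msg)
  class(cond) <- c(code, "example_error", class(cond))
  stop(cond)
}

schema_property <- function(graph, subject, local) {
  c(graph_objects(graph, subject, rdf_iri(paste0(SCHEMA_NS, local))),
    graph_objects(graph, subject, rdf_iri(paste0(SCHEMA_NS_HTTP, local))))
}

# Reads sh:prefixes declarations reachable from `node` in `graph`.
read_prefix_declarations <- function(graph, node) {
  decls <- graph_objects(graph, node, rdf_iri(paste0(SH_NS, "declare")))
  out <- character(0)
  for (d in decls) {
    label <- graph_objects(graph, d, rdf_iri(paste0(SH_NS, "prefix")))
    ns <- graph_objects(graph, d, rdf_iri(paste0(SH_NS, "namespace")))
    if (length(label) && length(ns)) {
      nsv <- if (term_type(ns[1L]) == "iri") iri_value(ns[1L]) else literal_parts(ns[1L])$value
      out[[literal_parts(label[1L])$value]] <- nsv
    }
  }
  out
}

#' Parse one Turtle example document
#'
#' @param turtle_text Turtle source describing exactly one example subject.
#' @param base_iri Optional base IRI for resolving relative IRIs.
#' @param extra_prefixes Named character vector merged into the document's
#'   prefix map after the file's own declarations (used by [load_collection()]
#'   to resolve a shared per-folder prefix node).
#' @return An [example_document()].
#' @export
parse_example <- function(turtle_text, base_iri = NULL, extra_prefixes = NULL) {
  graph <- tryCatch(parse_rdf(turtle_text, base = base_iri),
                    error = function(e) example_error("example_turtle_error",
                                                      paste0("malformed Turtle: ", conditionMessage(e))))
  query_props <- rdf_iri(unname(QUERY_KIND_PROPERTY))
  hits <- graph[graph$p %in% query_props, , drop = FALSE]
  subjects <- unique(hits$s)
  if (length(subjects) == 0L)
    example_error("example_missing_query", "no query property (sh:select/sh:ask/sh:construct/sh:update/spex:describe) found")
  if (length(subjects) > 1L)
    example_error("example_structure_error",
                  paste0("expected exactly one example subject, found ", length(subjects), ": ",
                         paste(subjects, collapse = ", ")))
  example_from_subject(graph, subjects, extra_prefixes = extra_prefixes)
}

# Extracts the example rooted at `subject` from an already-parsed graph
# (shared by parse_example and the endpoint compliance checker).
example_from_subject <- function(graph, subject, extra_prefixes = NULL) {
  query_props <- rdf_iri(unname(QUERY_KIND_PROPERTY))
  hits <- graph[graph$p %in% query_props, , drop = FALSE]
  props <- unique(hits$p[hits$s == subject])
  if (length(props) > 1L)
    example_error("example_structure_error",
                  paste0("multiple query properties on one subject: ", paste(props, collapse = ", ")))
  kind <- names(QUERY_KIND_PROPERTY)[QUERY_KIND_PROPERTY == iri_value(props)]
  qobj <- graph_objects(graph, subject, props)
  if (length(qobj) > 1L)
    example_error("example_structure_error", "multiple query texts on one subject")
  query <- literal_parts(qobj)$value

  comments_terms <- graph_objects(graph, subject, rdf_iri(paste0(RDFS_NS, "comment")))
  comments <- data.frame(
    text = vapply(comments_terms, function(t) literal_parts(t)$value, character(1)),
    lang = vapply(comments_terms, function(t) literal_parts(t)$lang, character(1)),
    stringsAsFactors = FALSE)

  targets <- unname(vapply(schema_property(graph, subject, "target"), iri_value, character(1)))
  keywords <- unname(vapply(schema_property(graph, subject, "keywords"),
                            function(t) literal_parts(t)$value, character(1)))
  fed <- unname(vapply(graph_objects(graph, subject, rdf_iri(paste0(SPEX_NS, "federatesWith"))),
                       iri_value, character(1)))
  types <- graph_objects(graph, subject, rdf_iri(paste0(RDF_NS, "type")))

  pnode <- graph_objects(graph, subject, rdf_iri(paste0(SH_NS, "prefixes")))
  has_prefix_node <- length(pnode) > 0L
  prefixes <- character(0)
  if (has_prefix_node) prefixes <- read_prefix_declarations(graph, pnode[1L])
  if (!is.null(extra_prefixes)) {
    add <- extra_prefixes[setdiff(names(extra_prefixes), names(prefixes))]
    prefixes <- c(prefixes, add)
  }

  example_document(
    id = if (term_type(subject) == "iri") iri_value(subject) else NA_character_,
    kind = kind, query = query, comments = comments, targets = targets,
    keywords = keywords, federates_with = fed,
    prefixes = prefix_map(prefixes),
    declared_types = vapply(types, iri_value, character(1)),
    has_prefix_node = has_prefix_node)
}

# Returns NULL or the name of the first violated invariant.
example_invariant_violation <- function(doc) {
  if (is.na(doc$id) || !is_absolute_iri(doc$id)) return("identifier must be an absolute IRI")
  if (!nzchar(trimws(doc$query))) return("query text must be non-empty")
  if (!nrow(doc$comments)) return("at least one comment is required")
  if (!any(!is.na(doc$comments$lang))) return("at least one comment must carry a language tag")
  if (!length(doc$targets)) return("at least one target endpoint is required")
  if (!all(is_absolute_iri(doc$targets))) return("targets must be absolute IRIs")
  NULL
}

ttl_query_literal <- function(text) {
  if (grepl('"""', text, fixed = TRUE) || grepl("\\", text, fixed = TRUE))
    return(paste0('"', escape_string(text), '"'))
  if (grepl("\n", text, fixed = TRUE) || grepl('"', text, fixed = TRUE)) {
    if (endsWith(text, '"')) text <- paste0(substr(text, 1L, nchar(text) - 1L), '\\"')
    return(paste0('"""', text, '"""'))
  }
  paste0('"', escape_string(text), '"')
}

#' Serialize an example document as Turtle
#'
#' Emits the SHACL/Schema.org representation: the SHACL subtype matches the
#' query kind (a DESCRIBE example is typed `sh:SPARQLExecutable` only) and
#' each predicate-object pair sits on its own line.
#'
#' @param doc An [example_document()] satisfying the document invariants.
#' @return Turtle text.
#' @export
serialize_example <- function(doc) {
  violation <- example_invariant_violation(doc)
  if (!is.null(violation)) example_error("example_invalid", paste0("serialization refused: ", violation))
  header <- c(
    paste0("@prefix sh: <", SH_NS, "> ."),
    paste0("@prefix rdfs: <", RDFS_NS, "> ."),
    paste0("@prefix schema: <", SCHEMA_NS, "> ."))
  if (doc$kind == "describe" || length(doc$federates_with))
    header <- c(header, paste0("@prefix spex: <", SPEX_NS, "> ."))
  if (doc$has_prefix_node && length(doc$prefixes))
    header <- c(header, paste0("@prefix xsd: <", XSD, "> ."))

  types <- if (doc$kind == "describe") "sh:SPARQLExecutable"
           else paste0("sh:", sub(SH_NS, "", QUERY_KIND_SUBTYPE[[doc$kind]], fixed = TRUE), ", sh:SPARQLExecutable")
  lines <- paste0("    a ", types, " ;")
  for (i in seq_len(nrow(doc$comments))) {
    tag <- if (!is.na(doc$comments$lang[i])) paste0("@", doc$comments$lang[i]) else ""
    lines <- c(lines, paste0('    rdfs:comment "', escape_string(doc$comments$text[i]), '"', tag, " ;"))
  }
  prop <- if (doc$kind == "describe") "spex:describe" else paste0("sh:", doc$kind)
  lines <- c(lines, paste0("    ", prop, " ", ttl_query_literal(doc$query), " ;"))
  for (t in doc$targets) lines <- c(lines, paste0("    schema:target <", t, "> ;"))
  for (k in doc$keywords) lines <- c(lines, paste0('    schema:keywords "', escape_string(k), '" ;'))
  for (f in doc$federates_with) lines <- c(lines, paste0("    spex:federatesWith <", f, "> ;"))
  if (doc$has_prefix_node) lines <- c(lines, "    sh:prefixes _:sparql_examples_prefixes ;")
  lines[length(lines)] <- sub(" ;$", " .", lines[length(lines)])

  decl_lines <- character(0)
  if (doc$has_prefix_node && length(doc$prefixes)) {
    decls <- vapply(seq_along(doc$prefixes), function(i)
      paste0('    sh:declare [ sh:prefix "', names(doc$prefixes)[i], '" ; sh:namespace "',
             doc$prefixes[[i]], '"^^xsd:anyURI ]'), character(1))
    decl_lines <- c("", "_:sparql_examples_prefixes",
                    paste0(paste(decls, collapse = " ;\n"), " ."))
  }
  paste(c(header, "", paste0("<", doc$id, ">"), lines, decl_lines, ""), collapse = "\n")
}

#' Construct an example collection
#'
#' @param examples List of [example_document()] objects.
#' @param resources Character vector, one resource (folder) name per example.
#' @param load_failures data.frame with columns `file` and `message`.
#' @param duplicates data.frame with columns `id`, `file`, `other_file`.
#' @return An object of class `example_collection`.
#' @export
example_collection <- function(examples, resources,
                               load_failures = data.frame(file = character(0), message = character(0),
                                                          stringsAsFactors = FALSE),
                               duplicates = data.frame(id = character(0), file = character(0),
                                                       other_file = character(0), stringsAsFactors = FALSE)) {
  stopifnot(length(examples) == length(resources))
  structure(list(examples = examples, resources = as.character(resources),
                 load_failures = load_failures, duplicates = duplicates),
            class = "example_collection")
}

#' @export
print.example_collection <- function(x, ...) {
  cat("<example_collection>", length(x$examples), "example(s) across",
      length(unique(x$resources)), "resource(s)\n")
  if (nrow(x$load_failures)) cat("  load failures:", nrow(x$load_failures), "\n")
  if (nrow(x$duplicates)) cat("  duplicate identifiers:", nrow(x$duplicates), "\n")
  invisible(x)
}

#' @export
length.example_collection <- function(x) length(x$examples)

#' Load a collection of examples from a folder tree
#'
#' Each immediate subfolder of `root` is a resource; every `.ttl` file in it is
#' one example. Files that define only shared prefix declarations (e.g. a
#' `prefixes.ttl` declaring the node referenced via `sh:prefixes`) are consumed
#' for prefix resolution and not emitted as examples. Unreadable or
#' non-conforming files are recorded as load failures, not raised.
#'
#' @param root Folder containing per-resource subfolders of .ttl files.
#' @param on_duplicate "error" raises a collection error naming both files of
#'   a duplicated identifier; "keep" records duplicates in the collection (so
#'   that validation can report them).
#' @return An [example_collection()].
#' @export
load_collection <- function(root, on_duplicate = c("error", "keep")) {
  on_duplicate <- match.arg(on_duplicate)
  if (!dir.exists(root)) stop("collection folder does not exist: ", root)
  resources <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  examples <- list(); res_of <- character(0); files <- character(0)
  failures <- data.frame(file = character(0), message = character(0), stringsAsFactors = FALSE)
  for (res in resources) {
    folder <- file.path(root, res)
    ttls <- sort(list.files(folder, pattern = "\\.ttl$", full.names = FALSE))
    # shared prefix resolution: non-example files contribute declarations
    shared <- character(0)
    example_files <- character(0)
    for (f in ttls) {
      path <- file.path(folder, f)
      txt <- tryCatch(paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n"),
                      error = function(e) NULL)
      if (is.null(txt)) {
        failures <- rbind(failures, data.frame(file = path, message = "unreadable file",
                                               stringsAsFactors = FALSE))
        next
      }
      is_example <- tryCatch({ parse_example(txt); TRUE },
        example_missing_query = function(e) FALSE,
        error = function(e) NA)
      if (isTRUE(is_example)) example_files <- c(example_files, f)
      else if (isFALSE(is_example)) {
        g <- tryCatch(parse_rdf(txt), error = function(e) NULL)
        if (!is.null(g)) {
          for (node in unique(g$s[g$p == rdf_iri(paste0(SH_NS, "declare"))]))
            shared <- c(shared, read_prefix_declarations(g, node))
          shared <- shared[!duplicated(names(shared))]
        }
      } else {
        msg <- tryCatch({ parse_example(txt); "" }, error = function(e) conditionMessage(e))
        failures <- rbind(failures, data.frame(file = path, message = msg, stringsAsFactors = FALSE))
      }
    }
    for (f in example_files) {
      path <- file.path(folder, f)
      txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
      doc <- parse_example(txt, extra_prefixes = if (length(shared)) shared else NULL)
      examples[[length(examples) + 1L]] <- doc
      res_of <- c(res_of, res)
      files <- c(files, path)
    }
  }
  ids <- vapply(examples, function(d) d$id, character(1))
  dup <- data.frame(id = character(0), file = character(0), other_file = character(0),
                    stringsAsFactors = FALSE)
  seen <- !is.na(ids) & duplicated(ids)
  if (any(seen)) {
    for (i in which(seen)) {
      first <- which(ids == ids[i])[1L]
      dup <- rbind(dup, data.frame(id = ids[i], file = files[i], other_file = files[first],
                                   stringsAsFactors = FALSE))
    }
    if (on_duplicate == "error")
      example_error("example_collection_error",
                    paste0("duplicate example identifier(s): ",
                           paste(sprintf("%s (%s and %s)", dup$id, dup$file, dup$other_file),
                                 collapse = "; ")))
  }
  coll <- example_collection(examples, res_of, load_failures = failures, duplicates = dup)
  coll$files <- files
  coll
}
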