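# Metadata and syntax validation of examples, plus execution probes.
#
# Rules (codes form a closed set):
#   R1 SYNTAX_ERROR            query must parse under the strict SPARQL 1.1
#                              grammar after prefix expansion; the parse is
#                              double-checked by re-parsing a serialization of
#                              the algebra (two independent passes)
#   R2 MISSING_ID / MISSING_TYPE / MISSING_COMMENT / MISSING_TARGET
#   R3 MISSING_LANGUAGE_TAG    at least one question carries a language tag
#   R4 TYPE_QUERY_MISMATCH     declared SHACL subtype vs query property vs
#                              parsed query form
#   R5 FEDERATED_WITHOUT_SERVICE  declared-federated queries must contain a
#                              SERVICE clause (checked on the parsed algebra,
#                              never on raw text)
#   R6 UNDECLARED_FEDERATION   SERVICE clause without a federation
#                              declaration (warning)
# Collection level: DUPLICATE_ID, LOAD_FAILURE.

VALIDATION_CODES <- c("SYNTAX_ERROR", "MISSING_ID", "MISSING_TYPE", "MISSING_COMMENT",
                      "MISSING_TARGET", "MISSING_LANGUAGE_TAG", "TYPE_QUERY_MISMATCH",
                      "FEDERATED_WITHOUT_SERVICE", "UNDECLARED_FEDERATION",
                      "DUPLICATE_ID", "LOAD_FAILURE")

validation_issue <- function(code, severity, subject, message, pointer = NA_character_) {
  stopifnot(code %in% VALIDATION_CODES)
  data.frame(code = code, severity = severity, subject = subject, message = message,
             pointer = pointer, stringsAsFactors = FALSE)
}

validation_report <- function(issues, examples_checked) {
  if (is.null(issues) || !length(issues)) {
    issues <- data.frame(code = character(0), severity = character(0), subject = character(0),
                         message = character(0), pointer = character(0), stringsAsFactors = FALSE)
  } else if (is.list(issues) && !is.data.frame(issues)) {
    issues <- do.call(rbind, issues)
  }
  structure(list(issues = issues, examples_checked = examples_checked,
                 passed = !any(issues$severity == "error")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", x$examples_checked, "example(s) checked:",
      if (x$passed) "PASSED" else "FAILED", "\n")
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s %s: %s\n", x$issues$severity[i], x$issues$code[i],
                  x$issues$subject[i], x$issues$message[i]))
  }
  invisible(x)
}

# TRUE when the example declares itself federated.
declares_federation <- function(doc) length(doc$federates_with) > 0L || "federated" %in% doc$keywords

query_has_service <- function(q) {
  found <- FALSE
  walk_pattern(q$where, function(node) if (identical(node$type, "service")) found <<- TRUE)
  found
}

# Strict parse with the dual-pass redundancy check; returns the query or a
# condition.
strict_parse <- function(query_text, prefixes = NULL) {
  q <- tryCatch(parse_sparql(query_text, extra_prefixes = prefixes %||% character(0)),
                error = function(e) e)
  if (inherits(q, "error")) return(q)
  if (q$form != "update") {
    second <- tryCatch(parse_sparql(sparql_serialize(q)), error = function(e) e)
    if (inherits(second, "error"))
      return(simpleError(paste0("algebra re-parse failed: ", conditionMessage(second))))
  }
  q
}

#' Validate a single example document
#'
#' Applies the metadata, syntax and consistency rules; all findings are
#' reported, never thrown.
#'
#' @param doc An [example_document()] (possibly violating invariants).
#' @param subject Label used in issue rows (defaults to the identifier).
#' @return A `validation_report`.
#' @export
validate_example <- function(doc, subject = NULL) {
  subj <- subject %||% (if (!is.na(doc$id)) doc$id else "<unidentified example>")
  issues <- list()
  add <- function(code, severity, message, pointer = NA_character_)
    issues[[length(issues) + 1L]] <<- validation_issue(code, severity, subj, message, pointer)

  # R2: mandatory fields
  if (is.na(doc$id)) add("MISSING_ID", "error", "example has no IRI identifier (blank node subject)")
  if (!length(doc$declared_types) || !any(startsWith(doc$declared_types, SH_NS)))
    add("MISSING_TYPE", "error", "no SHACL executable type declared", "rdf:type")
  if (!nrow(doc$comments))
    add("MISSING_COMMENT", "error", "no question/description (rdfs:comment) present", "rdfs:comment")
  if (!length(doc$targets))
    add("MISSING_TARGET", "error", "no target endpoint (schema:target) present", "schema:target")
  # R3: language tag
  if (nrow(doc$comments) && !any(!is.na(doc$comments$lang)))
    add("MISSING_LANGUAGE_TAG", "error", "no comment carries a language tag", "rdfs:comment")

  # R4 on the declared subtype vs the query property
  subtypes <- doc$declared_types[doc$declared_types %in% unname(QUERY_KIND_SUBTYPE)]
  for (tp in subtypes) {
    implied <- names(QUERY_KIND_SUBTYPE)[QUERY_KIND_SUBTYPE == tp]
    if (doc$kind == "describe")
      add("TYPE_QUERY_MISMATCH", "error",
          sprintf("a DESCRIBE example must be typed sh:SPARQLExecutable only, found %s", tp), "rdf:type")
    else if (implied != doc$kind)
      add("TYPE_QUERY_MISMATCH", "error",
          sprintf("declared type %s does not match query property sh:%s", tp, doc$kind), "rdf:type")
  }

  # R1: strict syntax (with prefix expansion from sh:prefixes)
  q <- strict_parse(doc$query, prefixes = doc$prefixes)
  if (inherits(q, "error")) {
    add("SYNTAX_ERROR", "error", conditionMessage(q), "query")
  } else {
    # R4 on the parsed query form
    if (q$form != doc$kind)
      add("TYPE_QUERY_MISMATCH", "error",
          sprintf("query property implies %s but the query text is a %s query",
                  doc$kind, toupper(q$form)), "query")
    # R5 / R6 on the parsed algebra
    has_service <- query_has_service(q)
    if (declares_federation(doc) && !has_service)
      add("FEDERATED_WITHOUT_SERVICE", "error",
          "example is declared federated but the query has no SERVICE clause", "query")
    if (has_service && !declares_federation(doc))
      add("UNDECLARED_FEDERATION", "warning",
          "query contains a SERVICE clause but is not declared federated", "query")
  }
  validation_report(issues, examples_checked = 1L)
}

#' Validate an example collection
#'
#' Union of the per-example reports plus collection-level rules: duplicate
#' identifiers and load failures are surfaced as errors.
#'
#' @param collection An [example_collection()].
#' @return A `validation_report`.
#' @export
validate_collection <- function(collection) {
  issues <- list()
  for (i in seq_along(collection$examples)) {
    subj <- if (!is.null(collection$files)) collection$files[i] else NULL
    rep <- validate_example(collection$examples[[i]], subject = subj)
    if (nrow(rep$issues)) issues[[length(issues) + 1L]] <- rep$issues
  }
  for (i in seq_len(nrow(collection$duplicates))) {
    d <- collection$duplicates[i, ]
    issues[[length(issues) + 1L]] <- validation_issue(
      "DUPLICATE_ID", "error", d$file,
      sprintf("identifier %s already used by %s", d$id, d$other_file), "identifier")
  }
  for (i in seq_len(nrow(collection$load_failures))) {
    f <- collection$load_failures[i, ]
    issues[[length(issues) + 1L]] <- validation_issue(
      "LOAD_FAILURE", "error", f$file, f$message, "file")
  }
  validation_report(issues, examples_checked = length(collection$examples))
}

#' Write a validation report as JSON
#'
#' @param report A `validation_report`.
#' @param path Output file (or NULL to return the JSON text).
#' @export
write_validation_report <- function(report, path = NULL) {
  payload <- list(passed = report$passed, examples_checked = report$examples_checked,
                  issues = report$issues)
  if (is.null(path)) return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## --------------------------------------------------------------------------
## execution probes

#' Rewrite a query so its effective result limit is exactly one
#'
#' The rewrite is textual and position-targeted: an existing top-level LIMIT
#' larger than the cap is overridden in place, otherwise a LIMIT clause is
#' appended; everything else in the query -- including comments -- is left
#' byte-identical. An existing `LIMIT 0` is kept and flagged.
#'
#' @param query_text SPARQL text of a SELECT/CONSTRUCT/DESCRIBE query.
#' @param limit The cap (1 for probes).
#' @return list(query, effective_limit, had_limit, kept_zero).
#' @export
rewrite_query_limit <- function(query_text, limit = 1L) {
  toks <- tokenize_rdf(query_text)
  depth <- 0L
  hit <- NULL
  for (i in seq_len(nrow(toks))) {
    t <- toks[i, ]
    if (t$text == "{") depth <- depth + 1L
    else if (t$text == "}") depth <- depth - 1L
    else if (depth == 0L && t$type == "IDENT" && toupper(t$text) == "LIMIT" &&
             i < nrow(toks) && toks$type[i + 1L] == "INTEGER")
      hit <- i
  }
  if (is.null(hit)) {
    return(list(query = paste0(sub("[ \t\n]+$", "", query_text), "\nLIMIT ", limit),
                effective_limit = limit, had_limit = FALSE, kept_zero = FALSE))
  }
  existing <- as.integer(toks$text[hit + 1L])
  if (existing == 0L)
    return(list(query = query_text, effective_limit = 0L, had_limit = TRUE, kept_zero = TRUE))
  if (existing <= limit)
    return(list(query = query_text, effective_limit = existing, had_limit = TRUE, kept_zero = FALSE))
  out <- paste0(substr(query_text, 1L, toks$start[hit + 1L] - 1L), limit,
                substr(query_text, toks$end[hit + 1L] + 1L, nchar(query_text)))
  list(query = out, effective_limit = limit, had_limit = TRUE, kept_zero = FALSE)
}

#' Probe that an example query retrieves at least one result
#'
#' SELECT/CONSTRUCT/DESCRIBE queries are rewritten with [rewrite_query_limit()]
#' so at most one result is requested; ASK queries run unchanged. Execution
#' happens against the supplied local graph unless `network_allowed` is TRUE
#' and `dataset` is an endpoint IRI. UPDATE examples are refused.
#'
#' @param doc An [example_document()].
#' @param dataset An [rdf_graph()], or an endpoint IRI string.
#' @param network_allowed Remote execution switch (default FALSE; probes are
#'   an on-demand tool, not part of routine validation).
#' @return list of class `probe_result`: `status` ("ok", "empty", "failed"),
#'   `reason`, `rewritten_query`, `kept_zero`.
#' @export
probe_example <- function(doc, dataset, network_allowed = FALSE) {
  if (doc$kind == "update") stop("refusing to execute an UPDATE example")
  remote <- is.character(dataset)
  if (remote && !network_allowed) {
    return(structure(list(status = "failed", reason = "network disabled",
                          rewritten_query = NA_character_, kept_zero = FALSE),
                     class = "probe_result"))
  }
  rewritten <- doc$query
  kept_zero <- FALSE
  if (doc$kind %in% c("select", "construct", "describe")) {
    rw <- rewrite_query_limit(doc$query, 1L)
    rewritten <- rw$query
    kept_zero <- rw$kept_zero
  }
  if (remote) {
    res <- tryCatch(remote_ask_rows(dataset, rewritten), error = function(e) e)
    if (inherits(res, "error")) {
      return(structure(list(status = "failed", reason = conditionMessage(res),
                            rewritten_query = rewritten, kept_zero = kept_zero),
                       class = "probe_result"))
    }
    return(structure(list(status = if (res) "ok" else "empty", reason = NA_character_,
                          rewritten_query = rewritten, kept_zero = kept_zero),
                     class = "probe_result"))
  }
  out <- tryCatch({
    q <- parse_sparql(rewritten, extra_prefixes = doc$prefixes %||% character(0))
    res <- sparql_eval(q, dataset)
    nonempty <- if (is.logical(res)) res else nrow(res) > 0L
    structure(list(status = if (nonempty) "ok" else "empty", reason = NA_character_,
                   rewritten_query = rewritten, kept_zero = kept_zero),
              class = "probe_result")
  }, error = function(e)
    structure(list(status = "failed", reason = conditionMessage(e),
                   rewritten_query = rewritten, kept_zero = kept_zero),
              class = "probe_result"))
  out
}

#' @export
print.probe_result <- function(x, ...) {
  cat("<probe_result>", x$status, if (!is.na(x$reason)) paste0("(", x$reason, ")"), "\n")
  invisible(x)
}

# Best-effort remote probe over the SPARQL protocol (only used on demand with
# network_allowed = TRUE; returns TRUE when at least one result came back).
remote_ask_rows <- function(endpoint, query) {
  u <- paste0(endpoint, if (grepl("\\?", endpoint)) "&" else "?",
              "query=", utils::URLencode(query, reserved = TRUE))
  con <- url(u, headers = c(Accept = "application/sparql-results+json"))
  on.exit(try(close(con), silent = TRUE))
  txt <- paste(readLines(con, warn = FALSE), collapse = "\n")
  res <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!is.null(res$boolean)) return(isTRUE(res$boolean))
  length(res$results$bindings) > 0L
}
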