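# VoID dataset descriptions, VoID-driven autocomplete, and endpoint metadata
# compliance checking.
#
# The VoID description records class partitions (distinct typed subjects),
# property partitions (triple counts) and a class/property linkage table:
# (subject class, property, object class or datatype, count). The object
# "class" is the object's rdf:type when typed, its literal datatype for
# literals, and an "unknown" marker otherwise; subjects with multiple types
# contribute a linkage row per type.

UNKNOWN_CLASS <- "unknown"

#' Generate a VoID description of an RDF dataset
#'
#' Partitions and linkage are computed by exhaustive counting over the graph.
#'
#' @param dataset An [rdf_graph()].
#' @param dataset_iri IRI naming the described dataset.
#' @return An object of class `void_description`: `dataset_iri`,
#'   `total_triples`, `class_partitions` (class, entities),
#'   `property_partitions` (property, triples) and `linkage`
#'   (subject_class, property, object_class, triples).
#' @export
generate_void <- function(dataset, dataset_iri) {
  rdf_type <- rdf_iri(paste0(RDF_NS, "type"))
  total <- nrow(dataset)

  types <- dataset[dataset$p == rdf_type & term_type(dataset$o) == "iri", c("s", "o"), drop = FALSE]
  class_partitions <- if (nrow(types)) {
    agg <- stats::aggregate(s ~ o, data = unique(types), FUN = length)
    data.frame(class = iri_value(agg$o), entities = agg$s, stringsAsFactors = FALSE)
  } else data.frame(class = character(0), entities = integer(0), stringsAsFactors = FALSE)
  class_partitions <- class_partitions[order(-class_partitions$entities, class_partitions$class), , drop = FALSE]

  property_partitions <- if (total) {
    agg <- stats::aggregate(list(n = seq_len(total)), by = list(p = dataset$p), FUN = length)
    data.frame(property = iri_value(agg$p), triples = agg$n, stringsAsFactors = FALSE)
  } else data.frame(property = character(0), triples = integer(0), stringsAsFactors = FALSE)
  property_partitions <- property_partitions[order(-property_partitions$triples, property_partitions$property), , drop = FALSE]

  linkage <- if (total) {
    sclass <- merge(data.frame(s = dataset$s, p = dataset$p, o = dataset$o, row = seq_len(total),
                               stringsAsFactors = FALSE),
                    stats::setNames(unique(types), c("s", "sclass")), by = "s", all.x = TRUE)
    # object classes: literals -> datatype; typed IRIs/bnodes -> each type; else unknown
    obj_lit <- term_type(sclass$o) == "literal"
    sclass$oclass <- NA_character_
    sclass$oclass[obj_lit] <- literal_datatype(sclass$o[obj_lit])
    omerge <- merge(sclass, stats::setNames(unique(types), c("o", "otype")), by = "o", all.x = TRUE)
    omerge$oclass <- ifelse(!is.na(omerge$oclass), omerge$oclass,
                            ifelse(!is.na(omerge$otype), iri_value(omerge$otype), UNKNOWN_CLASS))
    omerge$sclass <- ifelse(is.na(omerge$sclass), UNKNOWN_CLASS, iri_value(omerge$sclass))
    agg <- stats::aggregate(list(triples = omerge$row),
                            by = list(subject_class = omerge$sclass,
                                      property = iri_value(omerge$p),
                                      object_class = omerge$oclass),
                            FUN = function(x) length(unique(x)))
    agg[order(agg$subject_class, agg$property, agg$object_class), , drop = FALSE]
  } else data.frame(subject_class = character(0), property = character(0),
                    object_class = character(0), triples = integer(0), stringsAsFactors = FALSE)
  rownames(class_partitions) <- rownames(property_partitions) <- rownames(linkage) <- NULL

  structure(list(dataset_iri = dataset_iri, total_triples = total,
                 class_partitions = class_partitions,
                 property_partitions = property_partitions,
                 linkage = linkage), class = "void_description")
}

#' @export
print.void_description <- function(x, ...) {
  cat("<void_description>", x$dataset_iri, "\n")
  cat("  triples:", x$total_triples, "| classes:", nrow(x$class_partitions),
      "| properties:", nrow(x$property_partitions), "\n")
  invisible(x)
}

#' Serialize a VoID description as Turtle
#'
#' Standard VoID (void:triples, void:classPartition/void:entities,
#' void:propertyPartition/void:triples) plus the package's linkage
#' convention: each class partition nests property partitions that carry
#' `void:class` for the object class when known.
#'
#' @param void A [generate_void()] result.
#' @param path Optional output file.
#' @return Turtle text.
#' @export
serialize_void <- function(void, path = NULL) {
  lines <- c(
    paste0("@prefix void: <", VOID_NS, "> ."),
    paste0("@prefix xsd: <", XSD, "> ."),
    "",
    paste0("<", void$dataset_iri, "> a void:Dataset ;"),
    paste0("    void:triples ", void$total_triples, " ;"))
  pp <- void$property_partitions
  for (i in seq_len(nrow(pp)))
    lines <- c(lines, paste0("    void:propertyPartition [ void:property <", pp$property[i],
                             "> ; void:triples ", pp$triples[i], " ] ;"))
  cp <- void$class_partitions
  for (i in seq_len(nrow(cp))) {
    cls <- cp$class[i]
    link <- void$linkage[void$linkage$subject_class == cls, , drop = FALSE]
    inner <- vapply(seq_len(nrow(link)), function(k) {
      ocl <- link$object_class[k]
      extra <- if (ocl != UNKNOWN_CLASS) paste0(" ; void:class <", ocl, ">") else ""
      paste0("        void:propertyPartition [ void:property <", link$property[k],
             "> ; void:triples ", link$triples[k], extra, " ]")
    }, character(1))
    block <- paste0("    void:classPartition [ void:class <", cls, "> ; void:entities ",
                    cp$entities[i],
                    if (length(inner)) paste0(" ;\n", paste(inner, collapse = " ;\n"), "\n    ] ;")
                    else " ] ;")
    lines <- c(lines, block)
  }
  lines[length(lines)] <- sub(" ;$", " .", lines[length(lines)])
  ttl <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) writeLines(ttl, path)
  ttl
}

#' Autocomplete suggestions driven by a VoID description
#'
#' With a known focus class and `position = "predicate"`, only properties
#' that actually occur with that subject class are suggested; with
#' `position = "class"` all class-partition classes are candidates. The
#' partial input filters by case-insensitive prefix match against the CURIE
#' or the local name; ranking is by descending count, ties broken
#' lexicographically by IRI.
#'
#' @param void A [generate_void()] result.
#' @param focus_class IRI of the subject class in scope, or NULL/NA when
#'   unknown (falls back to all property partitions, flagged unscoped).
#' @param position "predicate" or "class".
#' @param partial Partial input typed so far.
#' @param prefixes Prefix map for CURIE display.
#' @return data.frame (class `completion_list`) with columns `iri`, `curie`,
#'   `count`; attribute `unscoped` marks the fallback.
#' @export
suggest_completions <- function(void, focus_class = NULL, position = c("predicate", "class"),
                                partial = "", prefixes = DEFAULT_DISPLAY_PREFIXES) {
  position <- match.arg(position)
  unscoped <- FALSE
  if (position == "class") {
    cand <- data.frame(iri = void$class_partitions$class,
                       count = void$class_partitions$entities, stringsAsFactors = FALSE)
  } else {
    known <- !is.null(focus_class) && !is.na(focus_class) &&
      focus_class %in% void$linkage$subject_class
    if (known) {
      link <- void$linkage[void$linkage$subject_class == focus_class, , drop = FALSE]
      agg <- stats::aggregate(triples ~ property, data = link, FUN = sum)
      cand <- data.frame(iri = agg$property, count = agg$triples, stringsAsFactors = FALSE)
    } else {
      unscoped <- TRUE
      cand <- data.frame(iri = void$property_partitions$property,
                         count = void$property_partitions$triples, stringsAsFactors = FALSE)
    }
  }
  cand$curie <- vapply(cand$iri, function(iri) {
    cur <- compact_iri(iri, prefixes)
    if (is.na(cur)) iri else cur
  }, character(1))
  if (nzchar(partial)) {
    pl <- tolower(partial)
    local <- tolower(sub("^.*[/#]", "", cand$iri))
    keep <- startsWith(tolower(cand$curie), pl) | startsWith(local, pl) |
      startsWith(tolower(sub("^[^:]*:", "", cand$curie)), pl)
    cand <- cand[keep, , drop = FALSE]
  }
  cand <- cand[order(-cand$count, cand$iri), c("iri", "curie", "count"), drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "unscoped") <- unscoped
  class(cand) <- c("completion_list", "data.frame")
  cand
}

#' Check an endpoint dump for required metadata
#'
#' Two checks: (C1) the dataset contains the well-known example named graph
#' for the endpoint with at least one well-formed example (validated with
#' [validate_example()]); (C2) a VoID description with at least one class
#' partition is present. Each failed check yields a concrete remediation
#' suggestion.
#'
#' @param dataset An [rdf_graph()] with named graphs (e.g. parsed from TriG),
#'   or a path to a TriG/Turtle file.
#' @param endpoint The endpoint IRI the dump belongs to.
#' @return list of class `compliance_report`: `has_examples_graph`,
#'   `has_void`, `example_count`, `suggestions`, `passed`.
#' @export
check_metadata_compliance <- function(dataset, endpoint) {
  if (is.character(dataset)) {
    if (!file.exists(dataset)) stop("unreadable input: ", dataset)
    dataset <- parse_rdf(paste(readLines(dataset, warn = FALSE, encoding = "UTF-8"), collapse = "\n"),
                         format = "trig")
  }
  giri <- named_graph_iri(endpoint)
  slice <- graph_slice(dataset, giri)
  example_count <- 0L
  invalid_examples <- 0L
  has_graph <- nrow(slice) > 0L
  if (has_graph) {
    query_props <- rdf_iri(unname(QUERY_KIND_PROPERTY))
    subjects <- unique(slice$s[slice$p %in% query_props])
    for (subj in subjects) {
      doc <- tryCatch(example_from_subject(slice, subj), error = function(e) NULL)
      ok <- !is.null(doc) && validate_example(doc)$passed
      if (ok) example_count <- example_count + 1L else invalid_examples <- invalid_examples + 1L
    }
  }
  has_examples <- example_count > 0L
  has_void <- any(dataset$p == rdf_iri(paste0(VOID_NS, "classPartition")))

  suggestions <- character(0)
  if (!has_examples)
    suggestions <- c(suggestions, paste0(
      "Publish at least one well-formed SPARQL example in the named graph <", giri,
      ">: merge the per-endpoint examples (merge_collection) and upload the resulting Turtle."))
  if (invalid_examples > 0L)
    suggestions <- c(suggestions, sprintf(
      "%d example(s) in <%s> fail validation; run the validator and fix the reported issues.",
      invalid_examples, giri))
  if (!has_void)
    suggestions <- c(suggestions, paste0(
      "Add a VoID description with class partitions for the endpoint's dataset ",
      "(generate_void() + serialize_void()) so schema-aware autocomplete can work."))
  structure(list(has_examples_graph = has_examples, has_void = has_void,
                 example_count = example_count, suggestions = suggestions,
                 passed = has_examples && has_void && invalid_examples == 0L),
            class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat("<compliance_report>", if (x$passed) "compliant" else "NOT compliant", "\n")
  cat("  examples graph:", x$has_examples_graph, "(", x$example_count, "valid example(s) )\n")
  cat("  VoID description:", x$has_void, "\n")
  for (s in x$suggestions) cat("  suggestion:", s, "\n")
  invisible(x)
}
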