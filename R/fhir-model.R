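# Version-specific serialization of the version-agnostic proxies.  Only
# this file knows the differences between the R4B and the R5 terminology
# resources; parsing, metadata interpretation and plugins are mode-blind
# apart from the mode gate on R5-only metadata paths.

#' FHIR serialization mode
#'
#' One compilation run uses exactly one FHIR version.  `R4B` also covers
#' R4: no changes between those two releases affect the terminology module.
#'
#' @param x `"R4B"` or `"R5"` (case-insensitive), or an `fhir_mode`.
#' @return a character scalar of class `fhir_mode`.
#' @export
fhir_mode <- function(x) {
  if (inherits(x, "fhir_mode")) {
    return(x)
  }
  v <- toupper(as.character(x))
  if (length(v) != 1L || !v %in% c("R4B", "R5")) {
    fsh_abort("invalid-mode",
              sprintf("FHIR mode must be 'R4B' or 'R5', got '%s'",
                      paste(x, collapse = ",")))
  }
  structure(v, class = "fhir_mode")
}

# properties the FHIR specification defines implicitly; using them requires
# no declaration and assemble() auto-declares them with their standard URIs
.implicit_properties <- list(
  parent = list(type = "code"),
  child = list(type = "code"),
  inactive = list(type = "boolean"),
  deprecated = list(type = "boolean"),
  notSelectable = list(type = "boolean")
)
.implicit_property_uri <- function(code) {
  paste0("http://hl7.org/fhir/concept-properties#", code)
}

.equivalence_r4b <- c("relatedto", "equivalent", "equal", "wider", "subsumes",
                      "narrower", "specializes", "inexact", "unmatched",
                      "disjoint")
.relationship_r5 <- c("related-to", "equivalent",
                      "source-is-narrower-than-target",
                      "source-is-broader-than-target", "not-related-to")

# --- element order tables --------------------------------------------------

.r5_meta_tail <- c("copyrightLabel", "approvalDate", "lastReviewDate",
                   "effectivePeriod", "topic", "author", "editor",
                   "reviewer", "endorser", "relatedArtifact")

element_order <- function(resource_type, mode) {
  head_common <- c("resourceType", "id", "meta", "implicitRules", "language",
                   "text", "url", "identifier", "version")
  version_alg <- if (mode == "R5") {
    c("versionAlgorithmString", "versionAlgorithmCoding")
  } else {
    character()
  }
  mid_common <- c("name", "title", "status", "experimental", "date",
                  "publisher", "contact", "description", "useContext",
                  "jurisdiction")
  switch(resource_type,
    CodeSystem = c(head_common, version_alg, mid_common,
                   "purpose", "copyright",
                   if (mode == "R5") .r5_meta_tail,
                   "caseSensitive", "valueSet", "hierarchyMeaning",
                   "compositional", "versionNeeded", "content",
                   "supplements", "count", "filter", "property", "concept"),
    ValueSet = c(head_common, version_alg, mid_common,
                 "immutable", "purpose", "copyright",
                 if (mode == "R5") .r5_meta_tail,
                 "compose", "expansion"),
    ConceptMap = c(head_common, version_alg, mid_common,
                   "purpose", "copyright",
                   if (mode == "R5") .r5_meta_tail,
                   if (mode == "R4B") c("sourceUri", "sourceCanonical",
                                        "targetUri", "targetCanonical"),
                   if (mode == "R5") c("property", "additionalAttribute",
                                       "sourceScopeUri", "sourceScopeCanonical",
                                       "targetScopeUri", "targetScopeCanonical"),
                   "group"),
    fsh_abort("invalid-mode",
              sprintf("unknown resource type '%s'", resource_type)))
}

# element names that exist in exactly one of the two modes; the serializer
# refuses to emit a name from the other mode's column
.mode_only_elements <- list(
  R5 = c("versionAlgorithmString", "versionAlgorithmCoding", .r5_meta_tail,
         "relationship", "noMap", "additionalAttribute",
         "sourceScopeUri", "sourceScopeCanonical",
         "targetScopeUri", "targetScopeCanonical"),
  R4B = c("equivalence", "sourceUri", "sourceCanonical",
          "targetUri", "targetCanonical")
)

# --- typed values -> JSON scalars ------------------------------------------

typed_to_json <- function(value) {
  switch(value$type_tag,
    string = ,
    multiline_string = ,
    datetime = ,
    canonical = as.character(value$parsed),
    code = as.character(value$parsed),
    boolean = as.logical(value$parsed),
    integer = as.integer(value$parsed),
    decimal = json_number(as.character(value$parsed)),
    fsh_abort("type-mismatch",
              sprintf("cannot serialize value of type '%s'", value$type_tag)))
}

property_value_pair <- function(code, value, type) {
  el <- switch(type,
    code = "valueCode", Coding = "valueCoding", string = "valueString",
    integer = "valueInteger", boolean = "valueBoolean",
    dateTime = "valueDateTime", decimal = "valueDecimal")
  v <- switch(type,
    code = as.character(value),
    Coding = value, # already a named list {system, code, display}
    string = as.character(value),
    integer = as.integer(value),
    boolean = as.logical(value),
    dateTime = as.character(value),
    decimal = json_number(as.character(value)))
  out <- list(code)
  names(out) <- "code"
  out[[el]] <- v
  out
}

# --- assembly --------------------------------------------------------------

#' Assemble a FHIR resource tree from metadata and content
#'
#' Combines [fsh_interpret_metadata()] output with a plugin's
#' [content_bundle()] into an abstract resource tree whose element names and
#' order follow the FHIR definition for the selected mode.  For a
#' CodeSystem, implicit properties used by any concept (`parent`, `child`,
#' `inactive`, `deprecated`, `notSelectable`) are auto-declared with their
#' standard URIs and `count` is set to the total number of concepts at all
#' nesting levels.
#'
#' @param meta a `term_resource_meta`.
#' @param bundle a `content_bundle` of the matching kind.
#' @param mode an [fhir_mode()].
#' @return a JSON tree (see [write_canonical_json()]) of class
#'   `fhir_resource` with attributes `resource_type` and `mode`.
#' @section Errors: `undeclared-property` (a concept uses a property that is
#'   neither declared nor implicit), `mode-vocabulary` (a ConceptMap
#'   correspondence code from the wrong mode's vocabulary; no automatic
#'   translation is attempted), `bundle-kind-mismatch`.
#' @export
assemble_resource <- function(meta, bundle, mode) {
  stopifnot(inherits(meta, "term_resource_meta"),
            inherits(bundle, "content_bundle"))
  mode <- fhir_mode(mode)
  if (!identical(meta$resource_kind, bundle$kind)) {
    fsh_abort("bundle-kind-mismatch",
              sprintf("metadata is for a %s but the bundle holds %s content",
                      meta$resource_kind, bundle$kind))
  }
  resource_type <- switch(meta$resource_kind, codesystem = "CodeSystem",
                          valueset = "ValueSet", conceptmap = "ConceptMap")
  fields <- meta_fields(meta, mode)
  fields$resourceType <- resource_type

  if (meta$resource_kind == "codesystem") {
    fields <- c(fields, codesystem_fields(meta, bundle$entries))
  } else if (meta$resource_kind == "valueset") {
    fields$compose <- compose_tree(bundle$entries)
  } else {
    fields$group <- groups_tree(bundle$entries, mode)
  }

  ord <- element_order(resource_type, mode)
  extra <- setdiff(names(fields), ord)
  if (length(extra)) {
    fsh_abort("unknown-path",
              sprintf("element(s) not in the %s %s definition: %s",
                      mode, resource_type, paste(extra, collapse = ", ")))
  }
  tree <- fields[ord[ord %in% names(fields)]]
  structure(tree, resource_type = resource_type, mode = as.character(mode),
            class = c("fhir_resource"))
}

meta_fields <- function(meta, mode) {
  fields <- list()
  set <- function(name, value) {
    if (!is.null(value) && !(length(value) == 1L && is.na(value))) {
      fields[[name]] <<- value
    }
  }
  set("id", meta$id)
  set("url", meta$url)
  set("version", meta$version)
  set("name", meta$name)
  set("title", meta$title)
  set("status", meta$status)
  set("experimental", meta$experimental)
  set("date", meta$date)
  set("publisher", meta$publisher)
  set("description", meta$description)
  set("copyright", meta$copyright)
  if (length(meta$identifiers)) {
    ids <- lapply(meta$identifiers, function(x) {
      x[intersect(c("use", "type", "system", "value"), names(x))]
    })
    fields$identifier <- json_array(ids)
  }
  extras <- c(meta$generic_extras,
              if (identical(as.character(mode), "R5")) meta$r5_extras)
  for (path in names(extras)) {
    fields <- set_tree_path(fields, split_path(path),
                            typed_to_json(extras[[path]]))
  }
  fields
}

# place a value at a dotted, optionally indexed path inside a tree
set_tree_path <- function(tree, segs, value) {
  seg <- segs[[1L]]
  if (is.na(seg$index)) {
    if (length(segs) == 1L) {
      tree[[seg$name]] <- value
    } else {
      sub <- tree[[seg$name]] %||% list()
      tree[[seg$name]] <- set_tree_path(sub, segs[-1L], value)
    }
    return(tree)
  }
  arr <- tree[[seg$name]] %||% json_array(list())
  slot <- seg$index + 1L
  while (length(arr) < slot) arr[[length(arr) + 1L]] <- list()
  if (length(segs) == 1L) {
    arr[[slot]] <- value
  } else {
    arr[[slot]] <- set_tree_path(arr[[slot]], segs[-1L], value)
  }
  tree[[seg$name]] <- json_array(unclass(arr))
  tree
}

codesystem_fields <- function(meta, concepts) {
  fields <- list()
  fields$caseSensitive <- if (!is.na(meta$case_sensitive)) meta$case_sensitive
  fields$hierarchyMeaning <-
    if (!is.na(meta$hierarchy_meaning)) meta$hierarchy_meaning
  fields$content <-
    if (!is.na(meta$content_mode)) meta$content_mode else "complete"
  fields$count <- count_concepts(concepts)

  declared <- character()
  decls <- list()
  for (d in meta$property_declarations) {
    if (is.na(d$code)) {
      fsh_abort("undeclared-property",
                "property declaration without a code (set property[i].code)")
    }
    entry <- list(code = d$code)
    if (!is.na(d$uri)) entry$uri <- d$uri
    entry$type <- if (!is.na(d$type)) d$type else "string"
    decls[[length(decls) + 1L]] <- entry
    declared <- c(declared, d$code)
  }

  used <- used_property_codes(concepts)
  for (code in used) {
    if (code %in% declared) next
    if (!code %in% names(.implicit_properties)) {
      fsh_abort("undeclared-property",
                sprintf("concept property '%s' is neither declared in the FSH source nor an implicit FHIR property (%s)",
                        code,
                        paste(names(.implicit_properties), collapse = ", ")))
    }
    decls[[length(decls) + 1L]] <- list(
      code = code, uri = .implicit_property_uri(code),
      type = .implicit_properties[[code]]$type)
    declared <- c(declared, code)
  }
  if (length(decls)) fields$property <- json_array(decls)
  if (length(concepts)) {
    fields$concept <- json_array(lapply(concepts, concept_tree))
  }
  Filter(Negate(is.null), fields)
}

count_concepts <- function(concepts) {
  total <- 0L
  for (c in concepts) {
    total <- total + 1L + count_concepts(c$children)
  }
  total
}

used_property_codes <- function(concepts) {
  gather <- function(cs) {
    unlist(lapply(cs, function(c) {
      own <- vapply(c$properties, `[[`, character(1), "code")
      if (length(c$children)) c(own, gather(c$children)) else own
    }), use.names = FALSE)
  }
  unique(gather(concepts) %||% character())
}

concept_tree <- function(concept) {
  node <- list(code = concept$code)
  if (!is.null(concept$display)) node$display <- concept$display
  if (!is.null(concept$definition)) node$definition <- concept$definition
  if (length(concept$designations)) {
    node$designation <- json_array(lapply(concept$designations, function(d) {
      out <- list()
      if (!is.null(d$language)) out$language <- d$language
      if (!is.null(d$use)) out$use <- d$use
      out$value <- d$value
      out
    }))
  }
  if (length(concept$properties)) {
    node$property <- json_array(lapply(concept$properties, function(p) {
      property_value_pair(p$code, p$value, p$type)
    }))
  }
  if (length(concept$children)) {
    node$concept <- json_array(lapply(concept$children, concept_tree))
  }
  node
}

compose_tree <- function(entries) {
  inc <- Filter(function(e) e$direction == "include", entries)
  exc <- Filter(function(e) e$direction == "exclude", entries)
  entry_tree <- function(e) {
    out <- list()
    if (!is.null(e$system)) out$system <- e$system
    if (!is.null(e$version)) out$version <- e$version
    if (length(e$concepts)) {
      out$concept <- json_array(lapply(e$concepts, function(c) {
        cc <- list(code = c$code)
        if (!is.null(c$display)) cc$display <- c$display
        cc
      }))
    }
    if (length(e$filters)) {
      out$filter <- json_array(lapply(e$filters, function(f) {
        list(property = f$property, op = f$op, value = f$value)
      }))
    }
    if (length(e$value_sets)) {
      out$valueSet <- json_array(as.list(e$value_sets))
    }
    out
  }
  compose <- list()
  if (length(inc)) compose$include <- json_array(lapply(inc, entry_tree))
  if (length(exc)) compose$exclude <- json_array(lapply(exc, entry_tree))
  compose
}

groups_tree <- function(groups, mode) {
  mode <- as.character(mode)
  vocab <- if (mode == "R4B") .equivalence_r4b else .relationship_r5
  corr_el <- if (mode == "R4B") "equivalence" else "relationship"
  json_array(lapply(groups, function(g) {
    out <- list()
    if (mode == "R4B") {
      out$source <- g$source
      if (!is.null(g$source_version)) out$sourceVersion <- g$source_version
      out$target <- g$target
      if (!is.null(g$target_version)) out$targetVersion <- g$target_version
    } else {
      # R5 carries the version inside the canonical reference
      out$source <- paste0(g$source,
                           if (!is.null(g$source_version))
                             paste0("|", g$source_version))
      out$target <- paste0(g$target,
                           if (!is.null(g$target_version))
                             paste0("|", g$target_version))
    }
    out$element <- json_array(lapply(g$elements, function(el) {
      node <- list(code = el$code)
      if (!is.null(el$display)) node$display <- el$display
      node$target <- json_array(lapply(el$targets, function(t) {
        if (!t$correspondence %in% vocab) {
          fsh_abort("mode-vocabulary",
                    sprintf("correspondence code '%s' is not in the %s %s vocabulary (%s); these codes are not translated automatically between FHIR versions",
                            t$correspondence, mode, corr_el,
                            paste(vocab, collapse = ", ")))
        }
        tn <- list(code = t$code)
        if (!is.null(t$display)) tn$display <- t$display
        tn[[corr_el]] <- t$correspondence
        if (!is.null(t$comment)) tn$comment <- t$comment
        tn
      }))
      node
    }))
    out
  }))
}

# --- serialization ---------------------------------------------------------

#' Serialize an assembled resource to canonical FHIR JSON
#'
#' Canonical form: UTF-8, `resourceType` first, element order following the
#' FHIR definition order for the mode, 2-space indentation, LF line endings,
#' no trailing whitespace, trailing newline.  Output is byte-deterministic
#' for equal inputs.  Before emitting, element names are checked against the
#' mode's allowlist: R4B output never contains R5-only names and vice versa.
#'
#' @param resource an [assemble_resource()] tree.
#' @param mode an [fhir_mode()]; must match the mode used at assembly.
#' @param path optional output path (written as bytes).
#' @return the JSON text (invisibly when `path` is given).
#' @export
serialize_fhir <- function(resource, mode, path = NULL) {
  mode <- fhir_mode(mode)
  if (!identical(attr(resource, "mode"), as.character(mode))) {
    fsh_abort("invalid-mode",
              sprintf("resource was assembled for %s but serialized as %s; one compilation run uses exactly one FHIR version",
                      attr(resource, "mode"), as.character(mode)))
  }
  check_mode_elements(resource, mode)
  tree <- unclass(resource)
  attributes(tree) <- list(names = names(tree))
  write_canonical_json(tree, path = path)
}

# Walk the tree checking element names against the other mode's exclusive
# names.  Arrays are sampled (first 50 elements) — assembly produces
# homogeneous arrays, so sampling is sufficient and keeps large code
# systems cheap to check.
check_mode_elements <- function(tree, mode) {
  banned <- .mode_only_elements[[if (as.character(mode) == "R4B") "R5" else "R4B"]]
  walk <- function(x) {
    if (!is.list(x)) {
      return(invisible())
    }
    nm <- names(x)
    if (!is.null(nm)) {
      bad <- intersect(nm, banned)
      if (length(bad)) {
        fsh_abort("mode-vocabulary",
                  sprintf("element(s) %s do not exist in FHIR %s",
                          paste(bad, collapse = ", "), as.character(mode)))
      }
    }
    n <- min(length(x), 50L)
    for (i in seq_len(n)) walk(x[[i]])
  }
  walk(tree)
  invisible()
}

#' @export
print.fhir_resource <- function(x, ...) {
  cat(sprintf("<fhir_resource> %s (%s)", attr(x, "resource_type"),
              attr(x, "mode")))
  if (!is.null(x$id)) cat(sprintf(" id=%s", x$id))
  if (!is.null(x$count)) cat(sprintf(" count=%d", x$count))
  cat("\n")
  invisible(x)
}
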