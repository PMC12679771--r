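#' Version-agnostic content containers
#'
#' Plugins never construct serialized FHIR; they emit these proxy content
#' items, which [assemble_resource()] later places into version-specific
#' element trees.  A [content_bundle()] is the kind-discriminated payload a
#' plugin returns: concept entries for a CodeSystem, compose entries for a
#' ValueSet, mapping groups for a ConceptMap.
#'
#' @param code concept code (non-empty string).
#' @param display,definition optional strings.
#' @param properties list of [concept_property()] values.
#' @param designations list of lists with `language`, optional `use`
#'   (a list with `system`/`code`/`display`) and `value`.
#' @param children nested child concepts (nested-hierarchy mode only).
#' @return the respective container object.
#' @export
concept_entry <- function(code, display = NULL, definition = NULL,
                          properties = list(), designations = list(),
                          children = list()) {
  if (!is.character(code) || length(code) != 1L || !nzchar(code)) {
    fsh_abort("empty-code", "concept code must be a non-empty string")
  }
  structure(list(code = code, display = display, definition = definition,
                 properties = properties, designations = designations,
                 children = children),
            class = "concept_entry")
}

#' @rdname concept_entry
#' @param value the property value (R scalar; decimals as character).
#' @param type one of `code`, `Coding`, `string`, `integer`, `boolean`,
#'   `dateTime`, `decimal`.
#' @export
concept_property <- function(code, value, type = "string") {
  stopifnot(type %in% .property_types)
  list(code = code, value = value, type = type)
}

#' @rdname concept_entry
#' @param direction `"include"` or `"exclude"`.
#' @param system,version optional code-system canonical and version.
#' @param concepts list of lists with `code` and optional `display`.
#' @param filters list of lists with `property`, `op`, `value`.
#' @param value_sets character vector of value-set canonicals.
#' @export
vs_compose_entry <- function(direction = c("include", "exclude"),
                             system = NULL, version = NULL,
                             concepts = list(), filters = list(),
                             value_sets = character()) {
  direction <- match.arg(direction)
  if (is.null(system) && length(value_sets) == 0L) {
    fsh_abort("vs-compose-invalid",
              "a compose entry needs a system and/or valueSet references")
  }
  if (length(concepts) && length(filters)) {
    fsh_abort("vs-compose-invalid",
              "a compose entry cannot combine enumerated concepts with filters")
  }
  structure(list(direction = direction, system = system, version = version,
                 concepts = concepts, filters = filters,
                 value_sets = value_sets),
            class = "vs_compose_entry")
}

#' @rdname concept_entry
#' @param source,target source/target code-system canonicals.
#' @param source_version,target_version optional versions.
#' @param elements list of lists with `code`, optional `display` and
#'   `targets` (each target: `code`, optional `display`, `correspondence`
#'   code, optional `comment`).
#' @export
cm_group <- function(source, target, elements,
                     source_version = NULL, target_version = NULL) {
  structure(list(source = source, source_version = source_version,
                 target = target, target_version = target_version,
                 elements = elements),
            class = "cm_group")
}

#' @rdname concept_entry
#' @param kind `"codesystem"`, `"valueset"` or `"conceptmap"`.
#' @param entries the kind's content items.
#' @export
content_bundle <- function(kind, entries) {
  kind <- match.arg(kind, c("codesystem", "valueset", "conceptmap"))
  expected <- switch(kind, codesystem = "concept_entry",
                     valueset = "vs_compose_entry", conceptmap = "cm_group")
  ok <- vapply(entries, inherits, logical(1), what = expected)
  if (!all(ok)) {
    fsh_abort("bundle-kind-mismatch",
              sprintf("%s bundle entries must all be <%s>", kind, expected))
  }
  structure(list(kind = kind, entries = entries), class = "content_bundle")
}

#' @export
print.content_bundle <- function(x, ...) {
  cat(sprintf("<content_bundle> %s with %d entr%s\n", x$kind,
              length(x$entries), if (length(x$entries) == 1L) "y" else "ies"))
  invisible(x)
}
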