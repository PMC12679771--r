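# Structural validation of assembled resources.  Findings are returned as
# issues, never raised: fatal/error issues prevent output writing, warnings
# never do.

#' Create a validation issue
#'
#' @param severity `"fatal"`, `"error"`, `"warning"` or `"info"`.
#' @param code stable machine-readable issue code (kebab-case).
#' @param message human-readable message.
#' @param file,line optional source location.
#' @param json_path optional location in the serialized resource.
#' @return an object of class `fsh_issue`.
#' @export
issue <- function(severity, code, message, file = NA_character_,
                  line = NA_integer_, json_path = NA_character_) {
  stopifnot(severity %in% c("fatal", "error", "warning", "info"))
  structure(list(severity = severity, code = code, message = message,
                 file = file, line = as.integer(line), json_path = json_path),
            class = "fsh_issue")
}

#' @rdname issue
#' @param issues a list of `fsh_issue`.
#' @return `issues_as_data_frame()` returns one row per issue.
#' @export
issues_as_data_frame <- function(issues) {
  data.frame(
    severity = vapply(issues, `[[`, character(1), "severity"),
    code = vapply(issues, `[[`, character(1), "code"),
    message = vapply(issues, `[[`, character(1), "message"),
    file = vapply(issues, `[[`, character(1), "file"),
    line = vapply(issues, `[[`, integer(1), "line"),
    json_path = vapply(issues, `[[`, character(1), "json_path"),
    stringsAsFactors = FALSE)
}

#' @export
print.fsh_issue <- function(x, ...) {
  loc <- if (!is.na(x$file)) {
    sprintf(" [%s%s]", x$file, if (!is.na(x$line)) paste0(":", x$line) else "")
  } else if (!is.na(x$json_path)) {
    sprintf(" [%s]", x$json_path)
  } else {
    ""
  }
  cat(sprintf("%s (%s): %s%s\n", toupper(x$severity), x$code, x$message, loc))
  invisible(x)
}

has_errors <- function(issues) {
  any(vapply(issues, function(i) i$severity %in% c("fatal", "error"),
             logical(1)))
}

#' Structurally validate an assembled resource
#'
#' Runs the structural checks of the terminology module against the
#' assembled tree and returns severity-tiered issues in stable order
#' (document order, then check order).  Validation is side-effect free; it
#' never raises.  A resource with zero error issues always serializes
#' successfully.
#'
#' Checks and their codes: `missing-status`, `invalid-url`,
#' `duplicate-code`, `undeclared-property`, `dangling-parent` (parent or
#' child values not resolving to a code; downgradable to a warning for
#' dangling parents explicitly allowed by the plugin),
#' `parent-cycle`, `concurrent-hierarchy` (warning), `name-convention`
#' (warning), `vs-compose-invalid`, `mode-vocabulary`, `empty-display`
#' (warning).
#'
#' @param resource an [assemble_resource()] tree.
#' @param mode an [fhir_mode()].
#' @param allow_dangling_parents downgrade dangling hierarchy references to
#'   warnings (set from the plugin's `--allow-dangling-parents`).
#' @return a list of [issue()] objects (possibly empty).
#' @export
validate_structure <- function(resource, mode,
                               allow_dangling_parents = FALSE) {
  mode <- fhir_mode(mode)
  type <- attr(resource, "resource_type")
  issues <- list()
  add <- function(severity, code, message, json_path = NA_character_) {
    issues[[length(issues) + 1L]] <<-
      issue(severity, code, message, json_path = json_path)
  }

  if (is.null(resource$status)) {
    add("error", "missing-status",
        sprintf("%s.status is required", type),
        json_path = paste0(type, ".status"))
  }
  if (!is.null(resource$url) &&
      !grepl("^([a-z][a-z0-9+.-]*:|urn:)[^[:space:]]+$", resource$url)) {
    add("error", "invalid-url",
        sprintf("'%s' is not a syntactically valid canonical URL",
                resource$url),
        json_path = paste0(type, ".url"))
  }
  if (!is.null(resource$name) &&
      !grepl("^[A-Z][A-Za-z0-9_]{0,254}$", resource$name)) {
    add("warning", "name-convention",
        sprintf("name '%s' does not follow the FHIR computable-name convention (PascalCase)",
                resource$name),
        json_path = paste0(type, ".name"))
  }

  if (type == "CodeSystem") {
    issues <- c(issues, validate_codesystem(resource, allow_dangling_parents))
  } else if (type == "ValueSet") {
    issues <- c(issues, validate_valueset(resource))
  } else if (type == "ConceptMap") {
    issues <- c(issues, validate_conceptmap(resource, mode))
  }
  issues
}

# flatten the (possibly nested) concept tree in document order;
# preallocated to stay linear on large code systems
flatten_concepts <- function(concept_array) {
  if (is.null(concept_array) || length(concept_array) == 0L) {
    return(list())
  }
  rec <- function(arr, depth) {
    do.call(c, lapply(arr, function(node) {
      own <- list(list(node = node, depth = depth))
      if (is.null(node$concept)) own else c(own, rec(node$concept, depth + 1L))
    }))
  }
  rec(concept_array, 1L)
}

validate_codesystem <- function(resource, allow_dangling_parents) {
  issues <- list()
  add <- function(severity, code, message, json_path = NA_character_) {
    issues[[length(issues) + 1L]] <<-
      issue(severity, code, message, json_path = json_path)
  }
  flat <- flatten_concepts(resource$concept)
  codes <- vapply(flat, function(x) x$node$code, character(1))
  nested <- any(vapply(flat, function(x) x$depth > 1L, logical(1)))

  dup <- unique(codes[duplicated(codes)])
  for (d in dup) {
    add("error", "duplicate-code",
        sprintf("concept code '%s' occurs %d times", d, sum(codes == d)),
        json_path = "CodeSystem.concept.code")
  }

  declared <- vapply(resource$property %||% list(),
                     function(p) p$code, character(1))

  # flatten all concept properties into parallel vectors (kept vectorized:
  # large code systems make per-concept membership tests quadratic)
  props <- lapply(flat, function(x) x$node$property)
  np <- vapply(props, length, integer(1))
  owner <- rep(codes, np)
  pl <- unlist(props, recursive = FALSE)
  pcode <- vapply(pl %||% list(), function(p) p$code, character(1))
  ptarget <- vapply(pl %||% list(),
                    function(p) p$valueCode %||% NA_character_, character(1))

  for (i in which(!pcode %in% declared)) {
    add("error", "undeclared-property",
        sprintf("concept '%s' uses undeclared property '%s'",
                owner[[i]], pcode[[i]]),
        json_path = "CodeSystem.concept.property")
  }

  hier <- pcode %in% c("parent", "child") & !is.na(ptarget)
  used_parent_child <- any(hier)
  dangling <- hier & !(ptarget %in% codes)
  for (i in which(dangling)) {
    add(if (allow_dangling_parents) "warning" else "error",
        "dangling-parent",
        sprintf("concept '%s': %s '%s' names no concept in this code system",
                owner[[i]], pcode[[i]], ptarget[[i]]),
        json_path = "CodeSystem.concept.property")
  }

  disp <- vapply(flat, function(x) x$node$display %||% NA_character_,
                 character(1))
  for (i in which(!is.na(disp) & !nzchar(disp))) {
    add("warning", "empty-display",
        sprintf("concept '%s' has an empty display", codes[[i]]),
        json_path = "CodeSystem.concept.display")
  }

  is_parent <- pcode == "parent" & !is.na(ptarget)
  is_child <- pcode == "child" & !is.na(ptarget)
  edges <- data.frame(
    from = c(owner[is_parent], ptarget[is_child]),
    to = c(ptarget[is_parent], owner[is_child]),
    stringsAsFactors = FALSE)
  cycles <- detect_parent_cycles(edges)
  for (cy in cycles) {
    add("error", "parent-cycle",
        sprintf("hierarchy cycle: %s", paste(c(cy, cy[[1L]]),
                                             collapse = " -> ")),
        json_path = "CodeSystem.concept.property")
  }

  if (nested && used_parent_child) {
    add("warning", "concurrent-hierarchy",
        "nested concept elements and parent/child properties are used concurrently; the FHIR standard states they should not be combined",
        json_path = "CodeSystem.concept")
  }
  issues
}

#' Detect cycles in the concept hierarchy graph
#'
#' Finds every directed cycle in the code-to-parent graph.  Multiple
#' parents (poly-hierarchy) are legal and produce no finding; only true
#' cycles are reported.  Each strongly connected component with a cycle is
#' reported once, as the code list along the cycle starting from its
#' lexicographically smallest member.
#'
#' @param edges a data frame with `from` (child code) and `to` (parent
#'   code) columns, as induced by parent/child properties.
#' @return a list of character vectors (empty for forests and DAGs).
#' @export
detect_parent_cycles <- function(edges) {
  if (!nrow(edges)) {
    return(list())
  }
  self <- edges$from == edges$to
  cycles <- lapply(unique(edges$from[self]), function(x) x)
  edges <- edges[!self, , drop = FALSE]
  if (!nrow(edges)) {
    return(cycles)
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  for (k in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == k]
    if (length(members) < 2L) next
    cycles[[length(cycles) + 1L]] <- trace_cycle(edges, members)
  }
  cycles
}

# walk the cycle inside one strongly connected component, starting from its
# lexicographically smallest member, always taking the smallest in-SCC
# successor (deterministic tie-break)
trace_cycle <- function(edges, members) {
  start <- sort(members)[[1L]]
  path <- start
  cur <- start
  repeat {
    nxt <- sort(edges$to[edges$from == cur & edges$to %in% members])
    cur <- nxt[[1L]]
    if (cur == start) {
      return(path)
    }
    if (cur %in% path) {
      # entered a sub-loop not through start; report from first revisit
      i <- match(cur, path)
      return(path[seq(i, length(path))])
    }
    path <- c(path, cur)
  }
}

validate_valueset <- function(resource) {
  issues <- list()
  entries <- c(resource$compose$include %||% list(),
               resource$compose$exclude %||% list())
  for (e in entries) {
    if (is.null(e$system) && is.null(e$valueSet)) {
      issues[[length(issues) + 1L]] <- issue(
        "error", "vs-compose-invalid",
        "compose entry has neither a system nor valueSet references",
        json_path = "ValueSet.compose")
    }
    if (!is.null(e$concept) && !is.null(e$filter)) {
      issues[[length(issues) + 1L]] <- issue(
        "error", "vs-compose-invalid",
        "compose entry combines enumerated concepts with filters",
        json_path = "ValueSet.compose")
    }
    for (c in e$concept %||% list()) {
      if (!is.null(c$display) && !nzchar(c$display)) {
        issues[[length(issues) + 1L]] <- issue(
          "warning", "empty-display",
          sprintf("compose concept '%s' has an empty display", c$code),
          json_path = "ValueSet.compose.include.concept.display")
      }
    }
  }
  issues
}

validate_conceptmap <- function(resource, mode) {
  issues <- list()
  vocab <- if (as.character(mode) == "R4B") .equivalence_r4b else .relationship_r5
  el <- if (as.character(mode) == "R4B") "equivalence" else "relationship"
  for (g in resource$group %||% list()) {
    for (e in g$element %||% list()) {
      for (t in e$target %||% list()) {
        corr <- t[[el]]
        if (is.null(corr) || !corr %in% vocab) {
          issues[[length(issues) + 1L]] <- issue(
            "error", "mode-vocabulary",
            sprintf("mapping %s -> %s: '%s' is not a valid %s %s code",
                    e$code, t$code, corr %||% "<missing>",
                    as.character(mode), el),
            json_path = paste0("ConceptMap.group.element.target.", el))
        }
        if (!is.null(t$display) && !nzchar(t$display)) {
          issues[[length(issues) + 1L]] <- issue(
            "warning", "empty-display",
            sprintf("mapping target '%s' has an empty display", t$code),
            json_path = "ConceptMap.group.element.target.display")
        }
      }
    }
  }
  issues
}
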