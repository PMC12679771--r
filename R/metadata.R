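# Interpretation of FSH rules into version-agnostic resource metadata.
#
# The supported metadata surface is deliberately a strict allowlist: every
# caret/assignment path must be known for the item kind, so that typos fail
# at compile time instead of producing invalid FHIR.

.status_codes <- c("draft", "active", "retired", "unknown")
.property_types <- c("code", "Coding", "string", "integer", "boolean",
                     "dateTime", "decimal")

# paths that only exist in the R5 terminology resources
.r5_only_roots <- c("editor", "reviewer", "author", "endorser", "topic",
                    "approvalDate", "lastReviewDate", "effectivePeriod",
                    "copyrightLabel", "versionAlgorithmString")

# generic paths retained verbatim for serialization (known-FHIR, unmapped)
.generic_paths <- list(
  codesystem = c("purpose", "language", "compositional", "versionNeeded",
                 "valueSet", "supplements"),
  valueset   = c("purpose", "language", "immutable"),
  conceptmap = c("purpose", "language")
)

#' Interpret item rules into version-agnostic resource metadata
#'
#' Maps keyword metadata (`Id:`, `Title:`, `Description:`, the item name)
#' and caret/assignment rules onto the resource-level metadata surface:
#' `^url`, `^version`, `^status`, `^experimental`, `^date`, `^publisher`,
#' `^copyright`, `^content`, `^caseSensitive`, `^hierarchyMeaning`,
#' `^identifier[i].*`, `^property[i].{code,uri,type}` and, in R5 mode only,
#' paths such as `^editor`/`^reviewer`.  Later rules on the same path
#' overwrite earlier ones (last-one-wins, logged at info level).
#'
#' @param item an `fsh_item` with no unexpanded insert rules.
#' @param mode an [fhir_mode()] (`"R4B"` or `"R5"`).
#' @param aliases alias map of the owning document (used in messages only;
#'   alias resolution already happened at parse time).
#' @return an object of class `term_resource_meta`.
#' @section Errors: `unknown-path` (path not in the supported surface for
#'   the item kind), `mode-error` (R5-only path in R4B mode),
#'   `type-mismatch` (value type does not fit the element),
#'   `unexpanded-insert` (expansion was skipped).
#' @export
fsh_interpret_metadata <- function(item, mode, aliases = character()) {
  stopifnot(inherits(item, "fsh_item"))
  mode <- fhir_mode(mode)
  kind <- if (item$kind == "instance") "conceptmap" else item$kind

  kw <- function(k) {
    if (k %in% names(item$keyword_meta)) item$keyword_meta[[k]] else NA_character_
  }
  meta <- structure(list(
    resource_kind = kind,
    id = kw("Id"),
    url = NA_character_,
    version = NA_character_,
    name = item$name,
    title = kw("Title"),
    status = NA_character_,
    experimental = NA,
    date = NA_character_,
    publisher = NA_character_,
    description = kw("Description"),
    copyright = NA_character_,
    case_sensitive = NA,
    content_mode = NA_character_,
    hierarchy_meaning = NA_character_,
    identifiers = list(),
    property_declarations = list(),
    r5_extras = list(),
    generic_extras = list(),
    decl_line = item$decl_line
  ), class = "term_resource_meta")

  for (rule in item$rules) {
    if (identical(rule$variant, "insert")) {
      fsh_abort("unexpanded-insert",
                sprintf("item '%s' still contains an insert rule; expand RuleSets first",
                        item$name),
                line = rule$line)
    }
    meta <- apply_meta_rule(meta, rule, kind, mode, item$name)
  }
  meta
}

split_path <- function(path) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1L]]
  lapply(segs, function(s) {
    m <- regexec("^([A-Za-z][A-Za-z0-9]*)(\\[([0-9]+)\\])?$", s)
    g <- regmatches(s, m)[[1L]]
    list(name = g[[2L]],
         index = if (nzchar(g[[3L]])) as.integer(g[[4L]]) else NA_integer_)
  })
}

expect_type <- function(rule, allowed, what) {
  if (!rule$value$type_tag %in% allowed) {
    fsh_abort("type-mismatch",
              sprintf("'%s' expects a %s value, got %s ('%s')",
                      rule$path, what, rule$value$type_tag,
                      rule$value$raw_text),
              line = rule$line)
  }
  rule$value$parsed
}

note_overwrite <- function(meta_field, old, path, line) {
  if (!is.null(old) && !all(is.na(old))) {
    fsh_log("info", "line %d: '%s' overwrites an earlier value (last-one-wins)",
            line, path)
  }
}

apply_meta_rule <- function(meta, rule, kind, mode, item_name) {
  segs <- split_path(rule$path)
  root <- segs[[1L]]$name

  if (root %in% .r5_only_roots) {
    if (mode == "R4B") {
      fsh_abort("mode-error",
                sprintf("'%s' is an R5-only metadata path; it is unknown to the R4B validator. Switch to R5 mode or remove the rule.",
                        rule$path),
                line = rule$line)
    }
    meta$r5_extras[[rule$path]] <- rule$value
    return(meta)
  }

  simple <- function(field, allowed, what, extra_check = NULL) {
    v <- expect_type(rule, allowed, what)
    if (!is.null(extra_check)) extra_check(v)
    note_overwrite(field, meta[[field]], rule$path, rule$line)
    meta[[field]] <<- v
    meta
  }

  switch(root,
    url = return(simple("url", c("canonical", "string"), "URI")),
    version = return(simple("version", c("string", "integer", "decimal"),
                            "string")),
    status = {
      v <- expect_type(rule, "code", "code")
      if (!v %in% .status_codes) {
        fsh_abort("type-mismatch",
                  sprintf("status must be one of %s, got '#%s'",
                          paste(.status_codes, collapse = "/"), v),
                  line = rule$line)
      }
      note_overwrite("status", meta$status, rule$path, rule$line)
      meta$status <- v
      return(meta)
    },
    experimental = return(simple("experimental", "boolean", "boolean")),
    date = return(simple("date", c("datetime", "string"), "dateTime")),
    publisher = return(simple("publisher", "string", "string")),
    title = return(simple("title", c("string", "multiline_string"), "string")),
    name = return(simple("name", "string", "string")),
    description = return(simple("description",
                                c("string", "multiline_string"), "string")),
    copyright = return(simple("copyright",
                              c("string", "multiline_string"), "string")),
    content = {
      if (kind != "codesystem") {
        fsh_abort("unknown-path", "'content' only exists on CodeSystem",
                  line = rule$line)
      }
      v <- expect_type(rule, "code", "code")
      if (!v %in% c("not-present", "example", "fragment", "complete",
                    "supplement")) {
        fsh_abort("type-mismatch",
                  sprintf("invalid CodeSystem content mode '#%s'", v),
                  line = rule$line)
      }
      meta$content_mode <- v
      return(meta)
    },
    caseSensitive = {
      if (kind != "codesystem") {
        fsh_abort("unknown-path", "'caseSensitive' only exists on CodeSystem",
                  line = rule$line)
      }
      return(simple("case_sensitive", "boolean", "boolean"))
    },
    hierarchyMeaning = {
      if (kind != "codesystem") {
        fsh_abort("unknown-path",
                  "'hierarchyMeaning' only exists on CodeSystem",
                  line = rule$line)
      }
      v <- expect_type(rule, "code", "code")
      if (!v %in% c("grouped-by", "is-a", "part-of", "classified-with")) {
        fsh_abort("type-mismatch",
                  sprintf("invalid hierarchyMeaning '#%s'", v),
                  line = rule$line)
      }
      meta$hierarchy_meaning <- v
      return(meta)
    },
    identifier = {
      idx <- segs[[1L]]$index
      if (is.na(idx) || length(segs) != 2L ||
          !segs[[2L]]$name %in% c("system", "value", "use")) {
        fsh_abort("unknown-path",
                  sprintf("unsupported identifier path '%s' (use identifier[i].system/value/use)",
                          rule$path),
                  line = rule$line)
      }
      slot <- idx + 1L
      while (length(meta$identifiers) < slot) {
        meta$identifiers[[length(meta$identifiers) + 1L]] <- list()
      }
      fld <- segs[[2L]]$name
      v <- if (fld == "use") {
        u <- expect_type(rule, "code", "code")
        if (!u %in% c("usual", "official", "temp", "secondary", "old")) {
          fsh_abort("type-mismatch",
                    sprintf("invalid identifier use '#%s'", u),
                    line = rule$line)
        }
        u
      } else {
        expect_type(rule, c("string", "canonical"), "string or URI")
      }
      meta$identifiers[[slot]][[fld]] <- v
      return(meta)
    },
    property = {
      if (kind != "codesystem") {
        fsh_abort("unknown-path",
                  "property declarations only exist on CodeSystem",
                  line = rule$line)
      }
      idx <- segs[[1L]]$index
      if (is.na(idx) || length(segs) != 2L ||
          !segs[[2L]]$name %in% c("code", "uri", "type")) {
        fsh_abort("unknown-path",
                  sprintf("unsupported property path '%s' (use property[i].code/uri/type)",
                          rule$path),
                  line = rule$line)
      }
      slot <- idx + 1L
      while (length(meta$property_declarations) < slot) {
        meta$property_declarations[[length(meta$property_declarations) + 1L]] <-
          list(code = NA_character_, uri = NA_character_, type = NA_character_)
      }
      fld <- segs[[2L]]$name
      v <- if (fld == "uri") {
        expect_type(rule, c("canonical", "string"), "URI")
      } else {
        expect_type(rule, "code", "code")
      }
      if (fld == "type" && !v %in% .property_types) {
        fsh_abort("type-mismatch",
                  sprintf("invalid property type '#%s' (allowed: %s)",
                          v, paste(.property_types, collapse = ", ")),
                  line = rule$line)
      }
      meta$property_declarations[[slot]][[fld]] <- v
      return(meta)
    }
  )

  if (root %in% .generic_paths[[kind]]) {
    meta$generic_extras[[rule$path]] <- rule$value
    return(meta)
  }

  fsh_abort("unknown-path",
            sprintf("'%s' is not a supported metadata path for a %s item",
                    rule$path, kind),
            line = rule$line)
}

#' @export
print.term_resource_meta <- function(x, ...) {
  cat(sprintf("<term_resource_meta> %s '%s'\n", x$resource_kind, x$name))
  for (f in c("id", "url", "version", "status", "publisher")) {
    if (!is.na(x[[f]])) cat(sprintf("  %s: %s\n", f, x[[f]]))
  }
  if (length(x$property_declarations)) {
    cat(sprintf("  %d declared propert%s\n",
                length(x$property_declarations),
                if (length(x$property_declarations) == 1L) "y" else "ies"))
  }
  invisible(x)
}
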