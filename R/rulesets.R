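#' Expand insert rules against RuleSet definitions
#'
#' Replaces every `insert` rule of every item, in place and recursively, by
#' the body of the referenced RuleSet with textual `{parameter}`
#' substitution, following soft-parse semantics: the substituted text is
#' re-parsed as rules only after substitution.  Expanded rules carry the
#' insertion-site line in `line` and the line of the originating RuleSet
#' body row in `origin_line`.
#'
#' @param doc an [fsh_parse()] document.
#' @param rulesets the RuleSet namespace to resolve against; defaults to the
#'   document's own.  Compilation passes a project-wide namespace merged
#'   over all source files.
#' @return the document with all insert rules replaced; `$rulesets` is kept.
#' @section Errors: `unknown-ruleset` (undefined name), `arity-mismatch`
#'   (argument count differs from the parameter count), `ruleset-cycle`
#'   (a RuleSet inserts itself directly or transitively).
#' @export
fsh_expand_rulesets <- function(doc, rulesets = doc$rulesets) {
  stopifnot(inherits(doc, "fsh_document"))
  doc$items <- lapply(doc$items, function(item) {
    item$rules <- expand_rule_list(item$rules, rulesets, doc$aliases,
                                   item$kind, character())
    item
  })
  doc
}

expand_rule_list <- function(rules, rulesets, aliases, kind, stack) {
  out <- list()
  for (rule in rules) {
    if (!identical(rule$variant, "insert")) {
      out[[length(out) + 1L]] <- rule
      next
    }
    out <- c(out, expand_insert(rule, rulesets, aliases, kind, stack))
  }
  out
}

expand_insert <- function(rule, rulesets, aliases, kind, stack) {
  name <- rule$ruleset_name
  if (name %in% stack) {
    fsh_abort("ruleset-cycle",
              sprintf("RuleSet '%s' inserts itself (chain: %s)",
                      name, paste(c(stack, name), collapse = " -> ")),
              line = rule$line)
  }
  rs <- rulesets[[name]]
  if (is.null(rs)) {
    fsh_abort("unknown-ruleset",
              sprintf("insert references undefined RuleSet '%s'", name),
              line = rule$line)
  }
  if (length(rule$args) != length(rs$parameters)) {
    fsh_abort("arity-mismatch",
              sprintf("RuleSet '%s' takes %d parameter(s) (%s) but %d argument(s) given",
                      name, length(rs$parameters),
                      paste(rs$parameters, collapse = ", "),
                      length(rule$args)),
              line = rule$line)
  }
  out <- list()
  for (k in seq_along(rs$body)) {
    text <- rs$body[[k]]
    for (p in seq_along(rs$parameters)) {
      text <- gsub(paste0("{", rs$parameters[[p]], "}"), rule$args[[p]],
                   text, fixed = TRUE)
    }
    parsed <- parse_rule_body(text, rule$line, kind, aliases)
    parsed$origin_line <- rs$body_lines[[k]]
    if (identical(parsed$variant, "insert")) {
      out <- c(out, expand_insert(parsed, rulesets, aliases, kind,
                                  c(stack, name)))
    } else {
      out[[length(out) + 1L]] <- parsed
    }
  }
  out
}
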