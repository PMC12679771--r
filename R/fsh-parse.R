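#' Parse a terminology-focused FSH source document
#'
#' Parses the strict FSH subset used for terminology resources: `Alias:`
#' declarations, `CodeSystem:` / `ValueSet:` / `Instance:` (of `ConceptMap`)
#' items with `Id:` / `Title:` / `Description:` keywords, caret value rules,
#' `insert` rules, parameterized `RuleSet:` definitions, line (`//`) and
#' block (`/* */`) comments.  Content-generation directives embedded in
#' block comments are recognized and attached to the lexically enclosing
#' item (see [extract_directives()]); ordinary comments are discarded.
#'
#' Inline concept rules (`* #code "Display"`) and value-set inclusion rules
#' are rejected: resource content is produced exclusively by plugins, never
#' by core FSH language elements.
#'
#' The parse is total: it either returns a complete document or signals a
#' condition of class `fshforge_parse_error` carrying every positioned
#' error (`$errors`, each with `code`, `message`, 1-based `line`).
#'
#' @param text source characters (single string or vector of lines), UTF-8.
#' @param source_path path label used in messages; when `text` is missing
#'   the file at `source_path` is read.
#' @return an object of class `fsh_document` with fields `source_path`,
#'   `aliases` (named character, names carry the leading `$`), `rulesets`
#'   (named list), `items` (list of `fsh_item`), `line_count` and
#'   `orphan_directives`.
#' @examples
#' doc <- fsh_parse(c(
#'   "CodeSystem: Demo",
#'   "Id: demo",
#'   "* ^url = \"http://example.org/cs\""
#' ), source_path = "<demo>")
#' length(doc$items)
#' @export
fsh_parse <- function(text, source_path = "<text>") {
  if (missing(text)) {
    text <- fsh_read_file(source_path)
  }
  text <- paste(text, collapse = "\n")
  if (any(!validUTF8(text))) {
    fsh_abort("encoding-error",
              sprintf("%s is not valid UTF-8", source_path))
  }
  text <- sub("^\ufeff", "", text)
  parse_fsh_text(text, source_path)
}

fsh_read_file <- function(path) {
  if (!file.exists(path)) {
    fsh_abort("path-missing", sprintf("no such file: %s", path))
  }
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!all(validUTF8(txt))) {
    fsh_abort("encoding-error", sprintf("%s is not valid UTF-8", path))
  }
  gsub("\r\n", "\n", txt, fixed = TRUE)
}

# Keywords that open a new top-level declaration (end the previous extent).
.top_keywords <- c("Alias", "CodeSystem", "ValueSet", "Instance", "RuleSet")
# FSH keywords outside the supported subset, rejected with a targeted message.
.unsupported_keywords <- c("Profile", "Extension", "Logical", "Resource",
                           "Mapping", "Invariant")

parse_fsh_text <- function(text, source_path) {
  errors <- list()
  note <- function(code, message, line, column = NULL) {
    errors[[length(errors) + 1L]] <<-
      parse_error_record(code, message, line, column)
  }

  directives_raw <- tryCatch(extract_directives(text),
    fshforge_error = function(e) {
      note(e$code, conditionMessage(e), e$line %||% 1L)
      list()
    })

  masked <- mask_comments(text)
  lines <- strsplit(masked, "\n", fixed = TRUE)[[1L]]
  if (length(lines) == 0L) lines <- ""
  n <- length(lines)

  aliases <- character()
  alias_lines <- integer()
  rulesets <- list()
  items <- list()

  # open contexts
  cur_item <- NULL      # list(item fields..., rule_lines, rule_line_nums)
  cur_ruleset <- NULL   # list(name, parameters, body, body_lines, decl_line)

  close_item <- function() {
    if (is.null(cur_item)) return()
    it <- cur_item
    cur_item <<- NULL
    if (it$kind == "instance" && (is.na(it$instance_of))) {
      note("syntax-error",
           sprintf("Instance '%s' lacks an InstanceOf declaration", it$name),
           it$decl_line)
    }
    items[[length(items) + 1L]] <<- it
  }
  close_ruleset <- function() {
    if (is.null(cur_ruleset)) return()
    rs <- cur_ruleset
    cur_ruleset <<- NULL
    if (!is.null(rulesets[[rs$name]])) {
      note("duplicate-name",
           sprintf("RuleSet '%s' is declared more than once", rs$name),
           rs$decl_line)
      return()
    }
    # every {placeholder} in the body must name a declared parameter
    for (k in seq_along(rs$body)) {
      ph <- regmatches(rs$body[[k]],
                       gregexpr("\\{([A-Za-z][A-Za-z0-9_-]*)\\}", rs$body[[k]]))[[1L]]
      ph <- unique(gsub("[{}]", "", ph))
      bad <- setdiff(ph, rs$parameters)
      if (length(bad)) {
        note("undeclared-parameter",
             sprintf("RuleSet '%s' uses undeclared parameter(s): %s",
                     rs$name, paste0("{", bad, "}", collapse = ", ")),
             rs$body_lines[[k]])
      }
    }
    rulesets[[rs$name]] <<- structure(
      list(name = rs$name, parameters = rs$parameters, body = rs$body,
           body_lines = rs$body_lines, decl_line = rs$decl_line),
      class = "fsh_ruleset")
  }

  i <- 1L
  while (i <= n) {
    line <- lines[[i]]
    stripped <- trimws(line)
    if (stripped == "") { i <- i + 1L; next }

    kw <- sub("^([A-Za-z][A-Za-z0-9]*)\\s*:.*$", "\\1", stripped)
    has_kw <- grepl("^[A-Za-z][A-Za-z0-9]*\\s*:", stripped)
    rest <- if (has_kw) trimws(sub("^[A-Za-z][A-Za-z0-9]*\\s*:", "", stripped)) else ""

    if (has_kw && kw %in% .unsupported_keywords) {
      note("unsupported-keyword",
           sprintf("'%s:' items are outside the supported terminology subset of FSH (CodeSystem, ValueSet, Instance of ConceptMap, RuleSet, Alias)", kw),
           i)
      close_item(); close_ruleset()
      i <- i + 1L
      next
    }

    if (has_kw && kw == "Alias") {
      close_item(); close_ruleset()
      m <- regexec("^(\\$[A-Za-z][A-Za-z0-9_-]*)\\s*=\\s*(\\S+)$", rest)
      g <- regmatches(rest, m)[[1L]]
      if (length(g) == 0L) {
        note("syntax-error",
             "malformed Alias (expected 'Alias: $name = uri')", i)
      } else if (g[[2L]] %in% names(aliases)) {
        note("duplicate-name",
             sprintf("alias '%s' is declared more than once", g[[2L]]), i)
      } else {
        aliases[[g[[2L]]]] <- g[[3L]]
        alias_lines[[g[[2L]]]] <- i
      }
      i <- i + 1L
      next
    }

    if (has_kw && kw == "RuleSet") {
      close_item(); close_ruleset()
      m <- regexec("^([A-Za-z][A-Za-z0-9_-]*)\\s*(\\(([^)]*)\\))?\\s*$", rest)
      g <- regmatches(rest, m)[[1L]]
      if (length(g) == 0L) {
        note("syntax-error", "malformed RuleSet declaration", i)
        i <- i + 1L
        next
      }
      params <- character()
      if (nzchar(g[[3L]])) {
        params <- trimws(strsplit(g[[4L]], ",", fixed = TRUE)[[1L]])
        bad <- params[!grepl("^[A-Za-z][A-Za-z0-9_-]*$", params)]
        if (length(bad)) {
          note("syntax-error",
               sprintf("invalid RuleSet parameter name(s): %s",
                       paste(bad, collapse = ", ")), i)
        }
      }
      cur_ruleset <- list(name = g[[2L]], parameters = params,
                          body = character(), body_lines = integer(),
                          decl_line = i)
      i <- i + 1L
      next
    }

    if (has_kw && kw %in% c("CodeSystem", "ValueSet", "Instance")) {
      close_item(); close_ruleset()
      if (!grepl("^[A-Za-z][A-Za-z0-9_-]*$", rest)) {
        note("syntax-error",
             sprintf("malformed %s declaration (expected an identifier name)", kw), i)
        i <- i + 1L
        next
      }
      cur_item <- list(
        kind = tolower(if (kw == "Instance") "instance" else kw),
        name = rest,
        instance_of = NA_character_,
        usage = NA_character_,
        keyword_meta = character(),
        rule_lines = character(),
        rule_line_nums = integer(),
        rules = list(),
        directives = list(),
        decl_line = i)
      i <- i + 1L
      next
    }

    if (has_kw && kw %in% c("InstanceOf", "Usage", "Id", "Title", "Description")) {
      if (!is.null(cur_ruleset)) {
        note("syntax-error",
             sprintf("'%s:' is not allowed inside a RuleSet body", kw), i)
        i <- i + 1L
        next
      }
      if (is.null(cur_item)) {
        note("syntax-error",
             sprintf("'%s:' outside of an item declaration", kw), i)
        i <- i + 1L
        next
      }
      if (kw == "InstanceOf") {
        if (cur_item$kind != "instance") {
          note("syntax-error", "'InstanceOf:' is only valid after 'Instance:'", i)
        } else {
          if (rest != "ConceptMap") {
            note("unsupported-keyword",
                 sprintf("Instance of '%s' is not supported; only ConceptMap instances are compiled", rest),
                 i)
          }
          cur_item$instance_of <- rest
        }
        i <- i + 1L
        next
      }
      if (kw == "Usage") {
        cur_item$usage <- rest
        i <- i + 1L
        next
      }
      # Id / Title / Description keyword metadata
      if (kw %in% names(cur_item$keyword_meta)) {
        note("duplicate-keyword",
             sprintf("'%s:' appears more than once in item '%s'", kw, cur_item$name),
             i)
        i <- i + 1L
        next
      }
      if (kw == "Id") {
        if (!grepl("^[A-Za-z0-9][A-Za-z0-9.-]{0,63}$", rest)) {
          note("syntax-error",
               "malformed Id (FHIR ids use letters, digits, '-' and '.', max 64 chars)", i)
        } else {
          cur_item$keyword_meta[[kw]] <- rest
        }
        i <- i + 1L
        next
      }
      # Title / Description take a (possibly multiline) string
      joined <- join_multiline(lines, i, rest)
      val <- tryCatch(parse_string_value(joined$text, joined$first_line),
        fshforge_error = function(e) {
          note(e$code, conditionMessage(e), e$line %||% i)
          NULL
        })
      if (!is.null(val)) cur_item$keyword_meta[[kw]] <- val
      i <- joined$next_i
      next
    }

    if (grepl("^\\*", stripped)) {
      joined <- join_multiline(lines, i, stripped)
      if (!is.null(cur_ruleset)) {
        cur_ruleset$body <- c(cur_ruleset$body, joined$text)
        cur_ruleset$body_lines <- c(cur_ruleset$body_lines, i)
      } else if (!is.null(cur_item)) {
        cur_item$rule_lines <- c(cur_item$rule_lines, joined$text)
        cur_item$rule_line_nums <- c(cur_item$rule_line_nums, i)
      } else {
        note("syntax-error", "rule outside of an item or RuleSet", i)
      }
      i <- joined$next_i
      next
    }

    note("syntax-error",
         sprintf("unrecognized declaration: '%s'",
                 substr(stripped, 1L, 60L)), i)
    i <- i + 1L
  }
  close_item()
  close_ruleset()

  # item name uniqueness
  nm <- vapply(items, function(x) x$name, character(1))
  for (dup in unique(nm[duplicated(nm)])) {
    dl <- vapply(items[nm == dup], function(x) x$decl_line, integer(1))
    note("duplicate-name",
         sprintf("item '%s' is declared more than once", dup), dl[[2L]])
  }

  # parse the collected rule lines of each item
  for (k in seq_along(items)) {
    it <- items[[k]]
    rules <- vector("list", length(it$rule_lines))
    for (j in seq_along(it$rule_lines)) {
      rules[[j]] <- tryCatch(
        parse_rule_body(it$rule_lines[[j]], it$rule_line_nums[[j]],
                        it$kind, aliases),
        fshforge_error = function(e) {
          note(e$code, conditionMessage(e),
               e$line %||% it$rule_line_nums[[j]])
          NULL
        })
    }
    it$rules <- Filter(Negate(is.null), rules)
    it$rule_lines <- NULL
    it$rule_line_nums <- NULL
    items[[k]] <- it
  }

  # attach directives to the lexically enclosing item
  decl_lines <- vapply(items, function(x) x$decl_line, integer(1))
  other_decls <- vapply(rulesets, function(x) x$decl_line, integer(1))
  orphans <- list()
  for (d in directives_raw) {
    tok <- tryCatch(tokenize_directive(d$raw_body),
      fshforge_error = function(e) e)
    block <- list(
      plugin_id = if (inherits(tok, "condition")) NA_character_ else tok$plugin_id,
      argv = if (inherits(tok, "condition")) character() else tok$argv,
      start_line = d$start_line, end_line = d$end_line,
      tokenize_error = if (inherits(tok, "condition")) {
        list(code = tok$code, message = conditionMessage(tok))
      } else NULL)
    owner <- owning_item(d$start_line, decl_lines, other_decls)
    if (is.na(owner)) {
      block$owner_item <- NA_character_
      orphans[[length(orphans) + 1L]] <- block
    } else {
      block$owner_item <- items[[owner]]$name
      items[[owner]]$directives <-
        c(items[[owner]]$directives, list(block))
    }
  }

  items <- lapply(items, function(x) structure(x, class = "fsh_item"))

  if (length(errors)) {
    errors <- errors[order(vapply(errors, function(e) e$line %||% 0L, integer(1)))]
    fsh_abort_parse(errors, source_path)
  }

  structure(
    list(source_path = source_path, aliases = aliases, rulesets = rulesets,
         items = items, line_count = n, orphan_directives = orphans),
    class = "fsh_document")
}

# An item's lexical extent runs from its declaration line to the line before
# the next item/RuleSet/Alias declaration (or EOF).
owning_item <- function(line, item_decl_lines, other_decl_lines) {
  cand <- which(item_decl_lines <= line)
  if (length(cand) == 0L) {
    return(NA_integer_)
  }
  owner <- cand[[which.max(item_decl_lines[cand])]]
  boundaries <- c(item_decl_lines, other_decl_lines)
  after <- boundaries[boundaries > item_decl_lines[[owner]]]
  if (length(after) && min(after) <= line) {
    return(NA_integer_)
  }
  owner
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fsh_document <- function(x, ...) {
  cat(sprintf("<fsh_document> %s\n", x$source_path))
  cat(sprintf("  %d line(s), %d alias(es), %d RuleSet(s), %d item(s)\n",
              x$line_count, length(x$aliases), length(x$rulesets),
              length(x$items)))
  for (it in x$items) {
    cat(sprintf("  - %s %s (line %d, %d rule(s), %d directive(s))\n",
                it$kind, it$name, it$decl_line, length(it$rules),
                length(it$directives)))
  }
  invisible(x)
}

# --- comment masking -------------------------------------------------------

# Replace every comment (line comments, block comments including directive
# blocks) with spaces, preserving newlines so that line/column numbers of
# the remaining code are unchanged.  String literals are respected.
mask_comments <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  out <- chars
  state <- "code"   # code | string | mstring | block | line
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    nxt <- if (i < n) chars[[i + 1L]] else ""
    if (state == "code") {
      # '//' opens a line comment only at line start or after whitespace,
      # so unquoted URLs (http://...) in alias values survive
      prev <- if (i > 1L) chars[[i - 1L]] else "\n"
      if (ch == "/" && nxt == "/" && grepl("^[ \t\n]$", prev)) {
        state <- "line"; out[[i]] <- " "; out[[i + 1L]] <- " "; i <- i + 2L
      } else if (ch == "/" && nxt == "*") {
        state <- "block"; out[[i]] <- " "; out[[i + 1L]] <- " "; i <- i + 2L
      } else if (ch == "\"") {
        if (i + 2L <= n && nxt == "\"" && chars[[i + 2L]] == "\"") {
          state <- "mstring"; i <- i + 3L
        } else {
          state <- "string"; i <- i + 1L
        }
      } else {
        i <- i + 1L
      }
    } else if (state == "string") {
      if (ch == "\\") {
        i <- i + 2L
      } else if (ch == "\"" || ch == "\n") {
        state <- "code"; i <- i + 1L
      } else {
        i <- i + 1L
      }
    } else if (state == "mstring") {
      if (ch == "\"" && i + 2L <= n && nxt == "\"" && chars[[i + 2L]] == "\"") {
        state <- "code"; i <- i + 3L
      } else {
        i <- i + 1L
      }
    } else if (state == "block") {
      if (ch == "*" && nxt == "/") {
        out[[i]] <- " "; out[[i + 1L]] <- " "; state <- "code"; i <- i + 2L
      } else {
        if (ch != "\n") out[[i]] <- " "
        i <- i + 1L
      }
    } else { # line comment
      if (ch == "\n") {
        state <- "code"
      } else {
        out[[i]] <- " "
      }
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

# --- multiline string joining ----------------------------------------------

# If the line opens a triple-quoted string that does not close on the same
# line, consume subsequent lines until the closer.  Returns the joined text,
# the first line number and the index of the next unconsumed line.
join_multiline <- function(lines, i, this_text) {
  count3 <- function(s) {
    m <- gregexpr('"""', s, fixed = TRUE)[[1L]]
    if (m[[1L]] == -1L) 0L else length(m)
  }
  k <- count3(this_text)
  if (k != 1L) {
    return(list(text = this_text, first_line = i, next_i = i + 1L))
  }
  acc <- this_text
  j <- i + 1L
  while (j <= length(lines)) {
    acc <- paste(acc, lines[[j]], sep = "\n")
    if (count3(lines[[j]]) >= 1L) {
      return(list(text = acc, first_line = i, next_i = j + 1L))
    }
    j <- j + 1L
  }
  fsh_abort("syntax-error",
            "unterminated multiline string (missing closing \"\"\")",
            line = i)
}

# --- rule parsing ----------------------------------------------------------

.path_re <- "[A-Za-z][A-Za-z0-9]*(\\[[0-9]+\\])?(\\.[A-Za-z][A-Za-z0-9]*(\\[[0-9]+\\])?)*"

# Parse one rule (text beginning with '*').  `kind` gates which rule
# variants are legal.  Signals classed conditions on malformed input.
parse_rule_body <- function(text, line, kind, aliases) {
  body <- trimws(sub("^\\s*\\*\\s*", "", text))
  if (body == "") {
    fsh_abort("syntax-error", "empty rule", line = line)
  }

  # inline concept definitions are content, which belongs to plugins
  if (grepl('^(\\$?[A-Za-z0-9.#_-]*)?#', body) && !grepl("=", body)) {
    fsh_abort("inline-concept",
              "inline concept rules are not supported: CodeSystem content is generated by a plugin directive (/*^babelfsh ... ^babelfsh*/), not by FSH concept rules",
              line = line)
  }
  if (grepl("^(include|exclude)\\b", body) || grepl("\\bcodes from\\b", body)) {
    fsh_abort("inline-content",
              "value-set composition rules are not supported: ValueSet content is generated by a plugin directive, not by FSH rules",
              line = line)
  }

  m <- regexec("^insert\\s+([A-Za-z][A-Za-z0-9_-]*)\\s*(\\((.*)\\))?\\s*$", body)
  g <- regmatches(body, m)[[1L]]
  if (length(g)) {
    args <- character()
    if (nzchar(g[[3L]])) {
      args <- split_insert_args(g[[4L]], line)
    }
    return(structure(list(variant = "insert", ruleset_name = g[[2L]],
                          args = args, line = line, origin_line = NULL),
                     class = "fsh_rule"))
  }
  if (grepl("^insert\\b", body)) {
    fsh_abort("syntax-error", "malformed insert rule", line = line)
  }

  caret <- grepl("^\\^", body)
  if (caret && kind == "instance") {
    fsh_abort("syntax-error",
              "caret value rules are not valid in Instance items; use plain assignment rules",
              line = line)
  }
  if (!caret && kind != "instance") {
    fsh_abort("syntax-error",
              "plain assignment rules are only valid in Instance items; use '* ^path = value'",
              line = line)
  }
  stripped <- if (caret) sub("^\\^", "", body) else body
  m <- regexec(paste0("^(", .path_re, ")\\s*=\\s*(.*)$"), stripped)
  g <- regmatches(stripped, m)[[1L]]
  if (length(g) == 0L) {
    fsh_abort("syntax-error",
              sprintf("malformed rule (expected '* %spath = value')",
                      if (caret) "^" else ""),
              line = line)
  }
  path <- g[[2L]]
  value_text <- trimws(g[[length(g)]])
  value <- parse_fsh_value(value_text, aliases, line)
  structure(list(variant = if (caret) "caret_value" else "plain_assignment",
                 path = path, value = value, line = line, origin_line = NULL),
            class = "fsh_rule")
}

# Insert-rule arguments are comma separated; literal ',' and ')' inside an
# argument are escaped with a backslash.
split_insert_args <- function(text, line) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  args <- character()
  cur <- character()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "\\" && i < length(chars) &&
        chars[[i + 1L]] %in% c(",", ")", "\\")) {
      cur <- c(cur, chars[[i + 1L]])
      i <- i + 2L
      next
    }
    if (ch == ",") {
      args <- c(args, paste(cur, collapse = ""))
      cur <- character()
      i <- i + 1L
      next
    }
    cur <- c(cur, ch)
    i <- i + 1L
  }
  args <- c(args, paste(cur, collapse = ""))
  trimws(args)
}

# --- value parsing ---------------------------------------------------------

fsh_typed_value <- function(type_tag, raw_text, parsed,
                            system = NULL, display = NULL) {
  structure(list(type_tag = type_tag, raw_text = raw_text, parsed = parsed,
                 system = system, display = display),
            class = "fsh_value")
}

unescape_fsh_string <- function(s) {
  out <- character()
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[[i]]
    if (ch == "\\" && i < length(chars)) {
      nxt <- chars[[i + 1L]]
      out <- c(out, switch(nxt, n = "\n", t = "\t", r = "\r",
                           "\"" = "\"", "\\" = "\\", nxt))
      i <- i + 2L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

parse_string_value <- function(text, line) {
  v <- parse_fsh_value(text, character(), line)
  if (!v$type_tag %in% c("string", "multiline_string")) {
    fsh_abort("syntax-error", "expected a (multiline) string value",
              line = line)
  }
  v$parsed
}

# Minimal-common-indent trimming for triple-quoted strings.
trim_multiline <- function(content) {
  ls <- strsplit(content, "\n", fixed = TRUE)[[1L]]
  if (length(ls) == 0L) {
    return("")
  }
  if (trimws(ls[[1L]]) == "") ls <- ls[-1L]
  while (length(ls) && trimws(ls[[length(ls)]]) == "") {
    ls <- ls[-length(ls)]
  }
  if (length(ls) == 0L) {
    return("")
  }
  nonblank <- ls[trimws(ls) != ""]
  indents <- vapply(nonblank,
                    function(x) nchar(sub("^( *).*$", "\\1", x)),
                    integer(1))
  k <- if (length(indents)) min(indents) else 0L
  paste(substring(ls, k + 1L), collapse = "\n")
}

parse_fsh_value <- function(text, aliases, line) {
  if (grepl('^"""', text)) {
    m <- regexec('^"""(.*)"""\\s*$', text)
    g <- regmatches(text, m)[[1L]]
    if (length(g) == 0L) {
      # opening and closing on separate lines: strip first/last marker
      inner <- sub('^"""', "", text)
      if (!grepl('"""\\s*$', inner)) {
        fsh_abort("syntax-error", "unterminated multiline string", line = line)
      }
      inner <- sub('"""\\s*$', "", inner)
    } else {
      inner <- g[[2L]]
    }
    return(fsh_typed_value("multiline_string", text, trim_multiline(inner)))
  }
  if (grepl('^"', text)) {
    m <- regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*$', text, perl = TRUE)
    g <- regmatches(text, m)[[1L]]
    if (length(g) == 0L) {
      fsh_abort("syntax-error", "malformed string literal", line = line)
    }
    return(fsh_typed_value("string", text, unescape_fsh_string(g[[2L]])))
  }
  if (text %in% c("true", "false")) {
    return(fsh_typed_value("boolean", text, identical(text, "true")))
  }
  if (grepl("#", text, fixed = TRUE)) {
    m <- regexec(paste0(
      '^([^#\\s"]+)?#("(?:[^"\\\\]|\\\\.)*"|[^\\s"]+)',
      '(?:\\s+("(?:[^"\\\\]|\\\\.)*"))?\\s*$'), text, perl = TRUE)
    g <- regmatches(text, m)[[1L]]
    if (length(g) == 0L) {
      fsh_abort("syntax-error", "malformed code value", line = line)
    }
    system <- g[[2L]]
    code <- g[[3L]]
    display <- g[[4L]]
    if (grepl('^"', code)) code <- unescape_fsh_string(gsub('^"|"$', "", code))
    if (nzchar(display)) {
      display <- unescape_fsh_string(gsub('^"|"$', "", display))
    } else {
      display <- NULL
    }
    if (nzchar(system)) {
      if (grepl("^\\$", system)) {
        if (!system %in% names(aliases)) {
          fsh_abort("unknown-alias",
                    sprintf("unresolved alias '%s'", system), line = line)
        }
        system <- aliases[[system]]
      }
    } else {
      system <- NULL
    }
    return(fsh_typed_value("code", text, code,
                           system = system, display = display))
  }
  if (grepl("^[+-]?[0-9]+$", text)) {
    return(fsh_typed_value("integer", text, as.integer(text)))
  }
  if (grepl("^[+-]?[0-9]+\\.[0-9]+$", text)) {
    return(fsh_typed_value("decimal", text, text))
  }
  if (grepl("^[0-9]{4}(-[0-9]{2}(-[0-9]{2})?)?(T[0-9:.+Z-]+)?$", text)) {
    return(fsh_typed_value("datetime", text, text))
  }
  if (grepl("^\\$[A-Za-z][A-Za-z0-9_-]*$", text)) {
    if (!text %in% names(aliases)) {
      fsh_abort("unknown-alias", sprintf("unresolved alias '%s'", text),
                line = line)
    }
    return(fsh_typed_value("canonical", text, aliases[[text]]))
  }
  if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:[^[:space:]]+$", text)) {
    return(fsh_typed_value("canonical", text, text))
  }
  fsh_abort("syntax-error",
            sprintf("unparseable value: '%s'", substr(text, 1L, 40L)),
            line = line)
}
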