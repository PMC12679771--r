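# Built-in content plugins.  `delimited-table` is the flagship: it converts
# delimited text catalogs (CSV/TSV/pipe) into CodeSystem concepts with
# configurable code/display/property/hierarchy column mappings.  `code-list`
# (ValueSet) and `mapping-table` (ConceptMap) are small demonstrations of
# the same plugin contract.

delimited_table_args <- function() {
  list(
    arg_spec("--file", "-f", kind = "path", required = TRUE,
             help = "input file with the delimited concept table"),
    arg_spec("--delimiter", "-d", kind = "string", default = ",",
             help = "cell delimiter, exactly one character (TAB for a tab stop)"),
    arg_spec("--encoding", kind = "choice",
             choices = c("utf-8", "latin1"), default = "utf-8",
             help = "text encoding of the input file"),
    arg_spec("--no-header", kind = "flag",
             help = "the file has no header row; columns are referenced by 1-based index"),
    arg_spec("--code-column", kind = "string", default = "CODE",
             help = "column holding the concept code"),
    arg_spec("--display-column", kind = "string",
             help = "column holding the concept display"),
    arg_spec("--definition-column", kind = "string",
             help = "column holding the concept definition"),
    arg_spec("--property", kind = "key_value_pair", repeatable = TRUE,
             help = "property mapping CODE=COLUMN[:TYPE]; the property must be declared in the FSH metadata or be an implicit FHIR property"),
    arg_spec("--parent-column", kind = "string",
             help = "column whose non-empty cells become hierarchy links to the named parent code"),
    arg_spec("--inactive-column", kind = "string",
             help = "column flagging deprecated concepts (emits the boolean 'inactive' property)"),
    arg_spec("--inactive-true-values", kind = "string",
             default = "YES,Y,TRUE,1",
             help = "comma-separated cell values (case-insensitive) counted as inactive"),
    arg_spec("--hierarchy", kind = "choice",
             choices = c("parent", "child", "both", "nested"),
             default = "parent",
             help = "hierarchy representation: parent/child/both properties, or nested concept elements"),
    arg_spec("--comment-prefix", kind = "string",
             help = "lines starting with this character are skipped"),
    arg_spec("--strict-parents", kind = "flag", mutex_group = "dangling",
             help = "treat parent references to missing codes as errors (the default)"),
    arg_spec("--allow-dangling-parents", kind = "flag",
             mutex_group = "dangling",
             help = "downgrade parent references to missing codes from error to warning")
  )
}

#' Read a delimited concept table
#'
#' Rows are parsed with the configured single-character delimiter; the
#' header row is consumed when present; empty lines and comment-prefixed
#' lines are skipped; cell values are verbatim (no trimming).  CRLF and LF
#' files yield identical records.  RFC-4180 double-quote escaping is honored
#' for comma and semicolon delimiters; pipe and tab files are raw splits.
#'
#' @param path input file.
#' @param delimiter one character (`"TAB"` accepted for tab).
#' @param encoding `"utf-8"` or `"latin1"`.
#' @param has_header consume the first kept row as header?
#' @param comment_prefix optional prefix marking comment lines.
#' @return a list with `header` (or `NULL`), `cells` (character matrix),
#'   `lines` (1-based source line of each row) and `width`.
#' @section Errors: `file-missing`, `decode-error` (with byte offset),
#'   `ragged-row` (cell count mismatch, with line number).
#' @export
read_delimited_table <- function(path, delimiter = ",",
                                 encoding = c("utf-8", "latin1"),
                                 has_header = TRUE, comment_prefix = NULL) {
  encoding <- match.arg(encoding)
  delimiter <- normalize_delimiter(delimiter)
  if (!file.exists(path)) {
    fsh_abort("file-missing", sprintf("input file does not exist: %s", path))
  }
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  if (encoding == "latin1") {
    Encoding(txt) <- "latin1"
    txt <- enc2utf8(txt)
  } else {
    Encoding(txt) <- "UTF-8"
    if (!all(validUTF8(txt))) {
      # locate the first undecodable byte for the message
      off <- first_invalid_utf8(raw)
      fsh_abort("decode-error",
                sprintf("%s is not valid UTF-8 (first bad byte at offset %d)",
                        path, off))
    }
  }
  txt <- gsub("\r\n", "\n", txt, fixed = TRUE)
  txt <- sub("\n$", "", txt)
  all_lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  keep <- nzchar(all_lines)
  if (!is.null(comment_prefix)) {
    keep <- keep & !startsWith(all_lines, comment_prefix)
  }
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(list(header = NULL, cells = matrix(character(), 0L, 0L),
                lines = integer(), width = 0L))
  }
  lines <- all_lines[idx]

  if (delimiter %in% c(",", ";")) {
    rows <- lapply(lines, split_rfc4180, delim = delimiter)
  } else {
    # raw split; sentinel preserves trailing empty cells
    rows <- strsplit(paste0(lines, delimiter, "\x01"), delimiter,
                     fixed = TRUE)
    rows <- lapply(rows, function(r) r[-length(r)])
  }

  header <- NULL
  if (has_header) {
    header <- rows[[1L]]
    rows <- rows[-1L]
    idx <- idx[-1L]
  }
  width <- if (!is.null(header)) {
    length(header)
  } else if (length(rows)) {
    length(rows[[1L]])
  } else {
    0L
  }
  lens <- lengths(rows)
  bad <- which(lens != width)
  if (length(bad)) {
    fsh_abort("ragged-row",
              sprintf("line %d has %d cell(s), expected %d",
                      idx[[bad[[1L]]]], lens[[bad[[1L]]]], width),
              line = idx[[bad[[1L]]]])
  }
  cells <- if (length(rows)) {
    matrix(unlist(rows, use.names = FALSE), ncol = width, byrow = TRUE)
  } else {
    matrix(character(), 0L, width)
  }
  list(header = header, cells = cells, lines = idx, width = width)
}

normalize_delimiter <- function(d) {
  if (identical(toupper(d), "TAB")) d <- "\t"
  if (nchar(d) != 1L) {
    fsh_abort("invalid-argument-value",
              sprintf("delimiter must be exactly one character, got '%s'", d))
  }
  d
}

first_invalid_utf8 <- function(raw) {
  # bisect on the cumulative prefix; adequate for an error message
  for (i in seq_along(raw)) {
    if (!all(validUTF8(rawToChar(raw[seq_len(i)], multiple = FALSE)))) {
      return(i)
    }
  }
  length(raw)
}

# RFC-4180 split of one physical line (quoted cells do not span lines)
split_rfc4180 <- function(line, delim) {
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  cells <- character()
  cur <- character()
  in_q <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (in_q) {
      if (ch == "\"") {
        if (i < n && chars[[i + 1L]] == "\"") {
          cur <- c(cur, "\"")
          i <- i + 2L
        } else {
          in_q <- FALSE
          i <- i + 1L
        }
      } else {
        cur <- c(cur, ch)
        i <- i + 1L
      }
    } else if (ch == "\"" && length(cur) == 0L) {
      in_q <- TRUE
      i <- i + 1L
    } else if (ch == delim) {
      cells <- c(cells, paste(cur, collapse = ""))
      cur <- character()
      i <- i + 1L
    } else {
      cur <- c(cur, ch)
      i <- i + 1L
    }
  }
  c(cells, paste(cur, collapse = ""))
}

# resolve a column reference (header name, or 1-based index without header)
col_index <- function(ref, header, width, what) {
  if (is.null(header)) {
    if (!grepl("^[0-9]+$", ref)) {
      fsh_abort("invalid-argument-value",
                sprintf("%s: headerless tables are addressed by 1-based column index, got '%s'",
                        what, ref))
    }
    i <- as.integer(ref)
    if (i < 1L || i > width) {
      fsh_abort("invalid-argument-value",
                sprintf("%s: column index %d out of range 1..%d", what, i, width))
    }
    return(i)
  }
  i <- match(ref, header)
  if (is.na(i)) {
    fsh_abort("invalid-argument-value",
              sprintf("%s: no column named '%s' (header: %s)",
                      what, ref, paste(header, collapse = ", ")))
  }
  i
}

#' Convert table rows into CodeSystem concept entries
#'
#' One [concept_entry()] per distinct code, in first-appearance order.  Rows
#' sharing a code merge into one concept accumulating properties in row
#' order; merged rows that disagree on display or definition are an error.
#' Non-empty mapped property cells emit one typed property each; cells in
#' the inactive true-value set emit `inactive = true`; non-empty parent
#' cells emit hierarchy links according to the hierarchy mode.
#'
#' @param table a [read_delimited_table()] result.
#' @param mapping list produced by the plugin's argument parsing: fields
#'   `code`, `display`, `definition`, `parent`, `inactive` (column indices
#'   or `NA`), `property_mappings` (list of `list(code, col, type)`),
#'   `true_values`, `hierarchy`, `allow_dangling`.
#' @param declared named character of declared property types (code ->
#'   type) from the item metadata.
#' @return list with `concepts` (list of [concept_entry()], nested when
#'   `hierarchy = "nested"`) and `dangling` (codes referenced as parents
#'   but absent, empty unless allowed).
#' @export
rows_to_concepts <- function(table, mapping, declared = character()) {
  cells <- table$cells
  n <- nrow(cells)
  lines <- table$lines
  codes <- if (n) cells[, mapping$code] else character()

  blank <- which(!nzchar(codes))
  if (length(blank)) {
    fsh_abort("empty-code",
              sprintf("line %d has an empty code cell", lines[[blank[[1L]]]]),
              line = lines[[blank[[1L]]]])
  }

  get_col <- function(i) if (is.na(i)) NULL else cells[, i]
  displays <- get_col(mapping$display)
  definitions <- get_col(mapping$definition)
  parents <- get_col(mapping$parent)
  inactive_cells <- get_col(mapping$inactive)
  inactive_flag <- if (is.null(inactive_cells)) {
    rep(FALSE, n)
  } else {
    nzchar(inactive_cells) &
      (toupper(inactive_cells) %in% toupper(mapping$true_values))
  }

  # typed property values per mapping (empty cells emit nothing)
  prop_values <- lapply(mapping$property_mappings, function(pm) {
    v <- cells[, pm$col]
    convert_property_cells(v, pm, lines)
  })

  uniq <- !duplicated(codes)
  code_order <- codes[uniq]
  slot_of <- match(codes, code_order)

  # display/definition conflicts among merged rows
  if (any(!uniq)) {
    check_merge_conflict(codes, displays, "display", slot_of, lines)
    check_merge_conflict(codes, definitions, "definition", slot_of, lines)
  }

  hierarchy <- mapping$hierarchy
  code_set <- code_order
  dangling <- character()
  if (!is.null(parents)) {
    has_parent <- nzchar(parents)
    missing <- has_parent & !(parents %in% code_set)
    if (any(missing)) {
      i <- which(missing)[[1L]]
      if (!mapping$allow_dangling) {
        fsh_abort("dangling-parent",
                  sprintf("line %d: parent '%s' names no code in the table",
                          lines[[i]], parents[[i]]),
                  line = lines[[i]])
      }
      dangling <- unique(parents[missing])
    }
  }

  if (hierarchy == "nested" && length(mapping$property_mappings)) {
    pm_codes <- vapply(mapping$property_mappings, `[[`, character(1), "code")
    if (any(pm_codes %in% c("parent", "child"))) {
      fsh_abort("concurrent-hierarchy",
                "nested hierarchy mode cannot be combined with explicit parent/child property mappings: the FHIR standard forbids using both representations concurrently")
    }
  }

  # assemble per-concept pieces in row order
  n_out <- length(code_order)
  prop_acc <- vector("list", n_out)
  disp_out <- rep(NA_character_, n_out)
  def_out <- rep(NA_character_, n_out)
  first_line <- rep(NA_integer_, n_out)
  child_links <- vector("list", n_out)  # row-order child codes per parent slot
  parent_of <- rep(NA_character_, n_out)

  for (i in seq_len(n)) {
    s <- slot_of[[i]]
    if (is.na(first_line[[s]])) first_line[[s]] <- lines[[i]]
    if (!is.null(displays) && nzchar(displays[[i]]) && is.na(disp_out[[s]])) {
      disp_out[[s]] <- displays[[i]]
    }
    if (!is.null(definitions) && nzchar(definitions[[i]]) && is.na(def_out[[s]])) {
      def_out[[s]] <- definitions[[i]]
    }
    for (k in seq_along(prop_values)) {
      pv <- prop_values[[k]]
      if (!is.na(pv$keep[[i]])) {
        pm <- mapping$property_mappings[[k]]
        prop_acc[[s]] <- c(prop_acc[[s]],
                           list(concept_property(pm$code, pv$values[[i]],
                                                 pm$type)))
      }
    }
    if (inactive_flag[[i]]) {
      prop_acc[[s]] <- c(prop_acc[[s]],
                         list(concept_property("inactive", TRUE, "boolean")))
    }
    if (!is.null(parents) && nzchar(parents[[i]])) {
      p <- parents[[i]]
      if (hierarchy %in% c("parent", "both")) {
        prop_acc[[s]] <- c(prop_acc[[s]],
                           list(concept_property("parent", p, "code")))
      }
      if (hierarchy %in% c("child", "both")) {
        ps <- match(p, code_order)
        if (!is.na(ps)) {
          child_links[[ps]] <- c(child_links[[ps]], codes[[i]])
        }
      }
      if (hierarchy == "nested") {
        if (is.na(parent_of[[s]])) parent_of[[s]] <- p
      }
    }
  }

  for (s in seq_len(n_out)) {
    for (ch in child_links[[s]]) {
      prop_acc[[s]] <- c(prop_acc[[s]],
                         list(concept_property("child", ch, "code")))
    }
  }

  # property codes must be declared or implicit (checked once per mapping)
  for (pm in mapping$property_mappings) {
    if (!pm$code %in% names(declared) &&
        !pm$code %in% names(.implicit_properties)) {
      fsh_abort("undeclared-property",
                sprintf("property '%s' is neither declared in the FSH metadata nor an implicit FHIR property",
                        pm$code))
    }
  }

  concepts <- lapply(seq_len(n_out), function(s) {
    concept_entry(code_order[[s]],
                  display = if (!is.na(disp_out[[s]])) disp_out[[s]],
                  definition = if (!is.na(def_out[[s]])) def_out[[s]],
                  properties = prop_acc[[s]] %||% list())
  })

  if (hierarchy == "nested") {
    concepts <- nest_concepts(concepts, code_order, parent_of)
  }
  list(concepts = concepts, dangling = dangling)
}

check_merge_conflict <- function(codes, values, what, slot_of, lines) {
  if (is.null(values)) {
    return(invisible())
  }
  seen <- character(max(slot_of))
  seen[] <- NA_character_
  for (i in seq_along(codes)) {
    v <- values[[i]]
    if (!nzchar(v)) next
    s <- slot_of[[i]]
    if (is.na(seen[[s]])) {
      seen[[s]] <- v
    } else if (!identical(seen[[s]], v)) {
      fsh_abort("duplicate-code-conflict",
                sprintf("line %d: rows merged under code '%s' disagree on %s ('%s' vs '%s')",
                        lines[[i]], codes[[i]], what, seen[[s]], v),
                line = lines[[i]])
    }
  }
  invisible()
}

convert_property_cells <- function(v, pm, lines) {
  keep <- ifelse(nzchar(v), TRUE, NA)
  values <- as.list(v)
  if (pm$type == "integer") {
    bad <- which(nzchar(v) & !grepl("^[+-]?[0-9]+$", v))
    if (length(bad)) {
      fsh_abort("invalid-property-value",
                sprintf("line %d: '%s' is not an integer (property '%s')",
                        lines[[bad[[1L]]]], v[[bad[[1L]]]], pm$code),
                line = lines[[bad[[1L]]]])
    }
    values <- lapply(values, function(x) if (nzchar(x)) as.integer(x) else x)
  } else if (pm$type == "boolean") {
    lo <- tolower(v)
    truthy <- lo %in% c("true", "yes", "y", "1")
    falsy <- lo %in% c("false", "no", "n", "0")
    bad <- which(nzchar(v) & !truthy & !falsy)
    if (length(bad)) {
      fsh_abort("invalid-property-value",
                sprintf("line %d: '%s' is not a boolean (property '%s')",
                        lines[[bad[[1L]]]], v[[bad[[1L]]]], pm$code),
                line = lines[[bad[[1L]]]])
    }
    values <- as.list(truthy)
  } else if (pm$type == "decimal") {
    bad <- which(nzchar(v) & !grepl("^[+-]?[0-9]+(\\.[0-9]+)?$", v))
    if (length(bad)) {
      fsh_abort("invalid-property-value",
                sprintf("line %d: '%s' is not a decimal (property '%s')",
                        lines[[bad[[1L]]]], v[[bad[[1L]]]], pm$code),
                line = lines[[bad[[1L]]]])
    }
  }
  list(keep = keep, values = values)
}

nest_concepts <- function(concepts, code_order, parent_of) {
  children_of <- vector("list", length(concepts))
  roots <- integer()
  for (s in seq_along(concepts)) {
    p <- parent_of[[s]]
    ps <- if (is.na(p)) NA_integer_ else match(p, code_order)
    if (is.na(ps)) {
      roots <- c(roots, s)
    } else {
      children_of[[ps]] <- c(children_of[[ps]], s)
    }
  }
  build <- function(s) {
    c0 <- concepts[[s]]
    c0$children <- lapply(children_of[[s]], build)
    c0
  }
  lapply(roots, build)
}

# --- the plugin content functions ------------------------------------------

delimited_table_content <- function(parsed, meta, kind, base_dir) {
  v <- parsed$values
  path <- resolve_input_path(v[["--file"]], base_dir)
  has_header <- !isTRUE(v[["--no-header"]])
  table <- read_delimited_table(
    path, delimiter = v[["--delimiter"]], encoding = v[["--encoding"]],
    has_header = has_header, comment_prefix = v[["--comment-prefix"]])

  declared <- declared_property_types(meta)
  property_mappings <- lapply(v[["--property"]] %||% list(), function(kv) {
    spec <- kv$value
    type <- NULL
    if (grepl(":", spec, fixed = TRUE)) {
      type <- sub("^.*:", "", spec)
      spec <- sub(":[^:]*$", "", spec)
    }
    declared_type <- declared[[kv$name]] %||%
      .implicit_properties[[kv$name]]$type
    if (!is.null(type) && !type %in% .property_types) {
      fsh_abort("invalid-argument-value",
                sprintf("--property %s: unknown type '%s'", kv$name, type))
    }
    if (!is.null(type) && !is.null(declared_type) &&
        !identical(type, declared_type)) {
      fsh_abort("type-mismatch",
                sprintf("--property %s maps type '%s' but the property is declared as '%s'",
                        kv$name, type, declared_type))
    }
    list(code = kv$name, colref = spec,
         type = type %||% declared_type %||% "string")
  })

  mapping <- list(
    code = col_index(v[["--code-column"]], table$header, table$width,
                     "--code-column"),
    display = opt_col(v[["--display-column"]], table, "--display-column"),
    definition = opt_col(v[["--definition-column"]], table,
                         "--definition-column"),
    parent = opt_col(v[["--parent-column"]], table, "--parent-column"),
    inactive = opt_col(v[["--inactive-column"]], table, "--inactive-column"),
    true_values = strsplit(v[["--inactive-true-values"]], ",",
                           fixed = TRUE)[[1L]],
    hierarchy = v[["--hierarchy"]],
    allow_dangling = isTRUE(v[["--allow-dangling-parents"]]),
    property_mappings = lapply(property_mappings, function(pm) {
      pm$col <- col_index(pm$colref, table$header, table$width,
                          sprintf("--property %s", pm$code))
      pm
    }))

  res <- rows_to_concepts(table, mapping, declared)
  bundle <- content_bundle("codesystem", res$concepts)
  bundle$options <- list(allow_dangling_parents = mapping$allow_dangling,
                         dangling = res$dangling)
  bundle
}

declared_property_types <- function(meta) {
  out <- character()
  for (d in meta$property_declarations) {
    if (!is.na(d$code)) {
      out[[d$code]] <- if (!is.na(d$type)) d$type else "string"
    }
  }
  as.list(out)
}

opt_col <- function(ref, table, what) {
  if (is.null(ref)) {
    return(NA_integer_)
  }
  col_index(ref, table$header, table$width, what)
}

resolve_input_path <- function(path, base_dir) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base_dir, path)
}

code_list_content <- function(parsed, meta, kind, base_dir) {
  v <- parsed$values
  table <- read_delimited_table(
    resolve_input_path(v[["--file"]], base_dir),
    delimiter = v[["--delimiter"]], has_header = TRUE)
  ci <- col_index("CODE", table$header, table$width, "code-list")
  di <- match("DISPLAY", table$header)
  concepts <- lapply(seq_len(nrow(table$cells)), function(i) {
    out <- list(code = table$cells[[i, ci]])
    if (!is.na(di) && nzchar(table$cells[[i, di]])) {
      out$display <- table$cells[[i, di]]
    }
    out
  })
  entry <- vs_compose_entry(
    if (isTRUE(v[["--exclude"]])) "exclude" else "include",
    system = v[["--system"]], version = v[["--system-version"]],
    concepts = concepts)
  content_bundle("valueset", list(entry))
}

mapping_table_content <- function(parsed, meta, kind, base_dir) {
  v <- parsed$values
  table <- read_delimited_table(
    resolve_input_path(v[["--file"]], base_dir),
    delimiter = v[["--delimiter"]], has_header = TRUE)
  si <- col_index("SOURCE", table$header, table$width, "mapping-table")
  ti <- col_index("TARGET", table$header, table$width, "mapping-table")
  ri <- col_index("CORRESPONDENCE", table$header, table$width,
                  "mapping-table")
  com <- match("COMMENT", table$header)
  src_codes <- table$cells[, si]
  elements <- lapply(unique(src_codes), function(code) {
    rows <- which(src_codes == code)
    list(code = code, targets = lapply(rows, function(i) {
      t <- list(code = table$cells[[i, ti]],
                correspondence = table$cells[[i, ri]])
      if (!is.na(com) && nzchar(table$cells[[i, com]])) {
        t$comment <- table$cells[[i, com]]
      }
      t
    }))
  })
  group <- cm_group(source = v[["--source-system"]],
                    target = v[["--target-system"]],
                    elements = elements,
                    source_version = v[["--source-version"]],
                    target_version = v[["--target-version"]])
  content_bundle("conceptmap", list(group))
}

register_builtin_plugins <- function() {
  register_plugin(plugin_descriptor(
    id = "delimited-table",
    kinds = "codesystem",
    arguments = delimited_table_args(),
    summary = "convert a delimited text table (CSV/TSV/pipe) into CodeSystem concepts",
    content_fn = delimited_table_content))
  register_plugin(plugin_descriptor(
    id = "code-list",
    kinds = "valueset",
    arguments = list(
      arg_spec("--file", "-f", kind = "path", required = TRUE,
               help = "CSV file with CODE and optional DISPLAY columns"),
      arg_spec("--delimiter", "-d", kind = "string", default = ",",
               help = "cell delimiter"),
      arg_spec("--system", kind = "string", required = TRUE,
               help = "canonical URL of the code system the codes come from"),
      arg_spec("--system-version", kind = "string",
               help = "version of the code system"),
      arg_spec("--exclude", kind = "flag",
               help = "emit an exclude entry instead of an include entry")),
    summary = "enumerate a ValueSet composition from a code list file",
    content_fn = code_list_content))
  register_plugin(plugin_descriptor(
    id = "mapping-table",
    kinds = "conceptmap",
    arguments = list(
      arg_spec("--file", "-f", kind = "path", required = TRUE,
               help = "CSV file with SOURCE, TARGET, CORRESPONDENCE and optional COMMENT columns"),
      arg_spec("--delimiter", "-d", kind = "string", default = ",",
               help = "cell delimiter"),
      arg_spec("--source-system", kind = "string", required = TRUE,
               help = "canonical URL of the source code system"),
      arg_spec("--source-version", kind = "string",
               help = "source code system version"),
      arg_spec("--target-system", kind = "string", required = TRUE,
               help = "canonical URL of the target code system"),
      arg_spec("--target-version", kind = "string",
               help = "target code system version")),
    summary = "build one ConceptMap group from a source/target mapping table",
    content_fn = mapping_table_content))
  invisible()
}
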