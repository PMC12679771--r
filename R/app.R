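# CLI orchestration: source discovery, per-file compile pipeline, mode
# selection, output writing, logging and exit codes.

.source_ext_re <- "\\.(babel|babelfsh)\\.fsh$"

#' Discover compilable source files
#'
#' Directories are scanned recursively; only files with the `.babel.fsh` or
#' `.babelfsh.fsh` extensions are considered, sorted lexicographically by
#' path for determinism.  Explicitly listed files must match the extensions
#' too.
#'
#' @param paths files and/or directories.
#' @return sorted character vector of source files.
#' @section Errors: `path-missing` (a path does not exist, or an explicit
#'   file does not carry a source extension), `no-sources` (nothing
#'   matched).
#' @export
discover_sources <- function(paths) {
  out <- character()
  for (p in paths) {
    if (dir.exists(p)) {
      hits <- list.files(p, pattern = .source_ext_re, recursive = TRUE,
                         full.names = TRUE)
      out <- c(out, hits)
    } else if (file.exists(p)) {
      if (!grepl(.source_ext_re, p)) {
        fsh_abort("path-missing",
                  sprintf("'%s' is not a compilable source: files need the .babel.fsh or .babelfsh.fsh extension",
                          p))
      }
      out <- c(out, p)
    } else {
      fsh_abort("path-missing", sprintf("no such file or directory: %s", p))
    }
  }
  out <- sort(unique(out), method = "radix")
  if (length(out) == 0L) {
    fsh_abort("no-sources",
              "no .babel.fsh / .babelfsh.fsh source files found")
  }
  out
}

#' Compile configuration
#'
#' @param paths input files or directories.
#' @param fhir_version `"R4B"` or `"R5"`; exactly one mode per invocation.
#' @param out_dir output directory for the FHIR JSON files.
#' @param deep_validate optional external validator command, invoked per
#'   written file; non-zero exits are relayed as warnings, never as errors.
#' @param fail_fast stop at the first item-level error?
#' @param log_level `"debug"`, `"info"`, `"warning"` or `"error"`.
#' @return a `compile_config` list.
#' @export
compile_config <- function(paths, fhir_version, out_dir = "out",
                           deep_validate = NULL, fail_fast = FALSE,
                           log_level = "warning") {
  structure(list(paths = paths, mode = fhir_mode(fhir_version),
                 out_dir = out_dir, deep_validate = deep_validate,
                 fail_fast = fail_fast, log_level = log_level),
            class = "compile_config")
}

#' Compile source files into FHIR JSON resources
#'
#' The pipeline per item: parse, expand RuleSets (project-wide namespace),
#' interpret metadata, resolve the directive's plugin, parse its arguments,
#' generate content, assemble, validate structurally, serialize, write.
#' Items compile independently: one item's failure does not abort its
#' siblings unless `fail_fast`.  Every CodeSystem/ValueSet/ConceptMap item
#' must carry exactly one directive; a directive whose argument vector is
#' exactly `--help` prints the plugin help and skips the item.
#'
#' @inheritParams compile_config
#' @param config alternatively, a ready [compile_config()].
#' @return an object of class `fsh_compile_result`: `written` (paths),
#'   `issues` (list of [issue()]), `ok` (no error-severity issues).
#' @export
fsh_compile <- function(paths, fhir_version, out_dir = "out",
                        deep_validate = NULL, fail_fast = FALSE,
                        log_level = "warning", config = NULL) {
  cfg <- config %||% compile_config(paths, fhir_version, out_dir,
                                    deep_validate, fail_fast, log_level)
  old <- options(fshforge.log_level = cfg$log_level)
  on.exit(options(old))

  issues <- list()
  written <- character()
  add_issue <- function(x) issues[[length(issues) + 1L]] <<- x
  cond_issue <- function(e, file, line = NULL) {
    issue("error", e$code %||% "internal-error", conditionMessage(e),
          file = file, line = line %||% e$line %||% NA_integer_)
  }

  sources <- tryCatch(discover_sources(cfg$paths), fshforge_error = function(e) e)
  if (inherits(sources, "condition")) {
    add_issue(cond_issue(sources, NA_character_))
    return(compile_result(written, issues))
  }

  if (!dir.exists(cfg$out_dir) &&
      !dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)) {
    add_issue(issue("fatal", "output-dir",
                    sprintf("cannot create output directory '%s'", cfg$out_dir)))
    return(compile_result(written, issues))
  }

  # pass 1: parse everything; RuleSets share one project-wide namespace
  docs <- list()
  for (src in sources) {
    doc <- tryCatch(fsh_parse(source_path = src), fshforge_error = function(e) e)
    if (inherits(doc, "fshforge_parse_error")) {
      for (e in doc$errors) {
        add_issue(issue("error", e$code, e$message, file = src,
                        line = e$line %||% NA_integer_))
      }
    } else if (inherits(doc, "condition")) {
      add_issue(cond_issue(doc, src))
    } else {
      docs[[src]] <- doc
    }
  }
  if (cfg$fail_fast && has_errors(issues)) {
    return(compile_result(written, issues))
  }

  rulesets <- list()
  for (src in names(docs)) {
    for (nm in names(docs[[src]]$rulesets)) {
      if (!is.null(rulesets[[nm]])) {
        add_issue(issue("error", "duplicate-ruleset",
                        sprintf("RuleSet '%s' is defined in more than one source file", nm),
                        file = src,
                        line = docs[[src]]$rulesets[[nm]]$decl_line))
      } else {
        rulesets[[nm]] <- docs[[src]]$rulesets[[nm]]
      }
    }
  }

  # pass 2: compile items
  planned <- character()  # output names, for collision detection
  for (src in names(docs)) {
    res <- compile_document(docs[[src]], rulesets, cfg, planned)
    planned <- res$planned
    written <- c(written, res$written)
    issues <- c(issues, res$issues)
    if (cfg$fail_fast && has_errors(issues)) break
  }

  if (!is.null(cfg$deep_validate)) {
    for (f in written) {
      status <- tryCatch(
        system2(cfg$deep_validate, shQuote(f), stdout = FALSE, stderr = FALSE),
        error = function(e) -1L)
      if (!identical(status, 0L)) {
        add_issue(issue("warning", "deep-validation",
                        sprintf("external validator '%s' exited with status %s for %s",
                                cfg$deep_validate, status, f),
                        file = f))
      }
    }
  }

  compile_result(written, issues)
}

compile_result <- function(written, issues) {
  structure(list(written = written, issues = issues,
                 ok = !has_errors(issues)),
            class = "fsh_compile_result")
}

#' @export
print.fsh_compile_result <- function(x, ...) {
  cat(sprintf("<fsh_compile_result> %s: %d resource(s) written, %d issue(s)\n",
              if (x$ok) "ok" else "FAILED", length(x$written),
              length(x$issues)))
  for (i in x$issues) print(i)
  invisible(x)
}

compile_document <- function(doc, rulesets, cfg, planned) {
  src <- doc$source_path
  issues <- list()
  written <- character()
  add_issue <- function(x) issues[[length(issues) + 1L]] <<- x

  for (d in doc$orphan_directives) {
    add_issue(issue("error", "orphan-directive",
                    "directive is not inside any item's lexical extent",
                    file = src, line = d$start_line))
  }

  for (item in doc$items) {
    res <- tryCatch(
      compile_item(item, doc, rulesets, cfg, planned),
      fshforge_error = function(e) e)
    if (inherits(res, "condition")) {
      add_issue(issue("error", res$code %||% "internal-error",
                      conditionMessage(res), file = src,
                      line = res$line %||% item$decl_line))
      if (cfg$fail_fast) break
      next
    }
    issues <- c(issues, res$issues)
    planned <- res$planned
    if (!is.null(res$written)) written <- c(written, res$written)
    if (cfg$fail_fast && has_errors(issues)) break
  }
  list(written = written, issues = issues, planned = planned)
}

compile_item <- function(item, doc, rulesets, cfg, planned) {
  src <- doc$source_path
  issues <- list()

  if (length(item$directives) == 0L) {
    fsh_abort("missing-directive",
              sprintf("item '%s' has no content directive; every CodeSystem/ValueSet/ConceptMap item needs exactly one /*^babelfsh ... ^babelfsh*/ block",
                      item$name),
              line = item$decl_line)
  }
  if (length(item$directives) > 1L) {
    fsh_abort("multiple-directives",
              sprintf("item '%s' has %d content directives; exactly one is allowed",
                      item$name, length(item$directives)),
              line = item$directives[[2L]]$start_line)
  }
  d <- item$directives[[1L]]
  if (!is.null(d$tokenize_error)) {
    fsh_abort(d$tokenize_error$code,
              sprintf("item '%s': %s", item$name, d$tokenize_error$message),
              line = d$start_line)
  }

  item$rules <- expand_rule_list(item$rules, rulesets, doc$aliases,
                                 item$kind, character())
  meta <- fsh_interpret_metadata(item, cfg$mode, doc$aliases)

  descriptor <- withCallingHandlers(
    resolve_plugin(d$plugin_id),
    fshforge_error = function(e) {
      e$line <- e$line %||% d$start_line
      stop(e)
    })

  if (identical(d$argv, "--help")) {
    cat(render_plugin_help(descriptor), "\n", sep = "", file = stderr())
    issues[[length(issues) + 1L]] <-
      issue("info", "help-requested",
            sprintf("item '%s' requested plugin help; item skipped", item$name),
            file = src, line = d$start_line)
    return(list(issues = issues, planned = planned, written = NULL))
  }

  with_line <- function(expr) {
    withCallingHandlers(expr, fshforge_error = function(e) {
      e$line <- e$line %||% d$start_line
      stop(e)
    })
  }
  parsed <- with_line(parse_plugin_args(descriptor, d$argv))
  bundle <- with_line(generate_content(descriptor, parsed, meta,
                                       kind = meta$resource_kind,
                                       base_dir = dirname(src)))
  resource <- with_line(assemble_resource(meta, bundle, cfg$mode))

  allow_dangling <- isTRUE(bundle$options$allow_dangling_parents)
  found <- validate_structure(resource, cfg$mode,
                              allow_dangling_parents = allow_dangling)
  for (f in found) {
    f$file <- src
    if (is.na(f$line)) f$line <- item$decl_line
    issues[[length(issues) + 1L]] <- f
  }
  if (has_errors(found)) {
    return(list(issues = issues, planned = planned, written = NULL))
  }

  out_name <- sprintf("%s-%s.json", attr(resource, "resource_type"),
                      resource$id %||% resource$name %||% item$name)
  if (out_name %in% planned) {
    fsh_abort("duplicate-output",
              sprintf("output file '%s' would be written by more than one item",
                      out_name),
              line = item$decl_line)
  }
  planned <- c(planned, out_name)
  out_path <- file.path(cfg$out_dir, out_name)
  serialize_fhir(resource, cfg$mode, path = out_path)
  fsh_log("info", "wrote %s (%s '%s')", out_path,
          attr(resource, "resource_type"), item$name)
  list(issues = issues, planned = planned, written = out_path)
}

#' Command-line entry point
#'
#' `fshforge_main(c("compile", "--fhir-version", "r4b", "src/"))` mirrors
#' the installed `fshforge` script.  Subcommands: `compile` (sources to
#' FHIR JSON), `fixtures` (write a synthetic test table, see
#' [generate_table()]), `help`.  Diagnostics go to standard error as
#' structured log lines.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return exit code, invisibly: 0 on success, 1 on compile/validation
#'   errors, 2 on usage errors.
#' @export
fshforge_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fshforge compile --fhir-version {r4b,r5} [--out DIR]",
    "                [--deep-validate CMD] [--fail-fast] [--log-level LVL]",
    "                PATH [PATH ...]",
    "       fshforge fixtures --layout {hierarchy_csv,alpha_like} --rows N",
    "                [--seed N] --out FILE",
    "       fshforge help [PLUGIN]",
    sep = "\n")
  die_usage <- function(msg) {
    cat(sprintf("error: %s\n%s\n", msg, usage), file = stderr())
    invisible(2L)
  }
  if (length(argv) == 0L) {
    return(die_usage("no subcommand given"))
  }
  sub <- argv[[1L]]
  rest <- argv[-1L]

  if (sub == "help") {
    if (length(rest)) {
      d <- tryCatch(resolve_plugin(rest[[1L]]), fshforge_error = function(e) e)
      if (inherits(d, "condition")) {
        return(die_usage(conditionMessage(d)))
      }
      cat(render_plugin_help(d), "\n", sep = "")
    } else {
      cat(usage, "\n", sep = "")
      cat("registered plugins:", paste(registered_plugins(), collapse = ", "),
          "\n")
    }
    return(invisible(0L))
  }

  if (sub == "fixtures") {
    opts <- tryCatch(parse_cli_flags(rest, list(
      "--layout" = "value", "--rows" = "value", "--seed" = "value",
      "--out" = "value")), fshforge_error = function(e) e)
    if (inherits(opts, "condition")) {
      return(die_usage(conditionMessage(opts)))
    }
    if (is.null(opts$flags[["--layout"]]) || is.null(opts$flags[["--rows"]]) ||
        is.null(opts$flags[["--out"]])) {
      return(die_usage("fixtures needs --layout, --rows and --out"))
    }
    spec <- fixture_spec(rows = as.integer(opts$flags[["--rows"]]),
                         seed = as.integer(opts$flags[["--seed"]] %||% "1"),
                         layout = opts$flags[["--layout"]])
    manifest <- generate_table(spec, opts$flags[["--out"]])
    cat(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE), "\n",
        file = stderr())
    return(invisible(0L))
  }

  if (sub != "compile") {
    return(die_usage(sprintf("unknown subcommand '%s'", sub)))
  }
  opts <- tryCatch(parse_cli_flags(rest, list(
    "--fhir-version" = "value", "--out" = "value",
    "--deep-validate" = "value", "--log-level" = "value",
    "--fail-fast" = "switch")), fshforge_error = function(e) e)
  if (inherits(opts, "condition")) {
    return(die_usage(conditionMessage(opts)))
  }
  if (is.null(opts$flags[["--fhir-version"]])) {
    return(die_usage("--fhir-version {r4b,r5} is required; one invocation compiles exactly one FHIR version"))
  }
  if (!tolower(opts$flags[["--fhir-version"]]) %in% c("r4b", "r5")) {
    return(die_usage("--fhir-version must be r4b or r5"))
  }
  if (length(opts$positional) == 0L) {
    return(die_usage("no input paths given"))
  }
  result <- fsh_compile(
    opts$positional,
    fhir_version = opts$flags[["--fhir-version"]],
    out_dir = opts$flags[["--out"]] %||% "out",
    deep_validate = opts$flags[["--deep-validate"]],
    fail_fast = isTRUE(opts$flags[["--fail-fast"]]),
    log_level = opts$flags[["--log-level"]] %||% "info")
  for (i in result$issues) {
    cat(sprintf("[%s] %s (%s)%s\n", toupper(i$severity), i$message, i$code,
                if (!is.na(i$file)) {
                  sprintf(" at %s%s", i$file,
                          if (!is.na(i$line)) paste0(":", i$line) else "")
                } else {
                  ""
                }),
        file = stderr())
  }
  invisible(if (result$ok) 0L else 1L)
}

parse_cli_flags <- function(argv, spec) {
  flags <- list()
  positional <- character()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[[i]]
    if (grepl("^--", a)) {
      kind <- spec[[a]]
      if (is.null(kind)) {
        fsh_abort("unknown-flag", sprintf("unknown flag '%s'", a))
      }
      if (kind == "switch") {
        flags[[a]] <- TRUE
        i <- i + 1L
      } else {
        if (i == length(argv)) {
          fsh_abort("invalid-argument-value", sprintf("%s expects a value", a))
        }
        flags[[a]] <- argv[[i + 1L]]
        i <- i + 2L
      }
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

#' Write issues as a machine-readable findings file
#'
#' One JSON object per line (JSON lines), fields `severity`, `code`,
#' `message`, `file`, `line`, `json_path`.
#'
#' @param issues list of [issue()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_findings <- function(issues, path) {
  lines <- vapply(issues, function(i) {
    jsonlite::toJSON(i[c("severity", "code", "message", "file", "line",
                         "json_path")],
                     auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
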