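#' Declare a plugin argument
#'
#' Plugins declare their command-line arguments with long and (optionally)
#' short forms, a value kind, and a mandatory help text, from which the
#' framework derives both the parser and the generated help: every flag in
#' the help is accepted by the parser and vice versa.
#'
#' @param long the `--name` form (must start with `--`).
#' @param short optional `-x` form.
#' @param kind one of `string`, `integer`, `path`, `choice`, `flag`,
#'   `key_value_pair` (`NAME=VALUE`, split by the framework).
#' @param choices allowed values (kind `choice` only).
#' @param repeatable may the flag occur multiple times (values accumulate
#'   in order)?
#' @param required must the flag be given?  Required arguments cannot have
#'   a default; `flag` kinds cannot be required.
#' @param default value used when the flag is absent.
#' @param help help text shown in the generated help (mandatory).
#' @param mutex_group optional label; at most one member of a group may be
#'   given.
#' @return an object of class `fsh_arg_spec`.
#' @export
arg_spec <- function(long, short = NULL, kind = "string", choices = NULL,
                     repeatable = FALSE, required = FALSE, default = NULL,
                     help, mutex_group = NULL) {
  kind <- match.arg(kind, c("string", "integer", "path", "choice", "flag",
                            "key_value_pair"))
  stopifnot(grepl("^--[a-z][a-z0-9-]*$", long),
            is.null(short) || grepl("^-[a-zA-Z]$", short))
  if (missing(help) || !is.character(help) || !nzchar(help)) {
    stop("every plugin argument must carry a help text")
  }
  if (required && !is.null(default)) {
    stop(sprintf("%s: required arguments cannot have a default", long))
  }
  if (kind == "flag" && required) {
    stop(sprintf("%s: flag arguments cannot be required", long))
  }
  if (kind == "choice" && is.null(choices)) {
    stop(sprintf("%s: choice arguments need 'choices'", long))
  }
  if (kind == "flag" && is.null(default)) default <- FALSE
  structure(list(long = long, short = short, kind = kind, choices = choices,
                 repeatable = repeatable, required = required,
                 default = default, help = help, mutex_group = mutex_group),
            class = "fsh_arg_spec")
}

#' Describe a content plugin
#'
#' The plugin contract has exactly two entry points: the argument
#' declaration (the `arguments` list, parsed type-safely by the framework)
#' and the content generator `content_fn(args, meta, kind, base_dir)`, which
#' must return a [content_bundle()] of the owning item's kind.  Plugins
#' never see FHIR element names; they emit version-agnostic proxy content.
#'
#' @param id unique plugin id (no whitespace).
#' @param kinds subset of `c("codesystem", "valueset", "conceptmap")`.
#' @param arguments list of [arg_spec()].
#' @param summary one-line plugin description.
#' @param content_fn the content generator function.
#' @return an object of class `fsh_plugin`.
#' @export
plugin_descriptor <- function(id, kinds, arguments, summary, content_fn) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            !grepl("[[:space:]]", id),
            all(kinds %in% c("codesystem", "valueset", "conceptmap")),
            is.function(content_fn))
  longs <- vapply(arguments, `[[`, character(1), "long")
  if (anyDuplicated(longs)) {
    stop(sprintf("plugin '%s': duplicate long flag(s): %s", id,
                 paste(unique(longs[duplicated(longs)]), collapse = ", ")))
  }
  shorts <- unlist(lapply(arguments, `[[`, "short"))
  if (anyDuplicated(shorts)) {
    stop(sprintf("plugin '%s': duplicate short flag(s)", id))
  }
  structure(list(plugin_id = id, supported_kinds = kinds,
                 arguments = arguments, summary = summary,
                 content_fn = content_fn),
            class = "fsh_plugin")
}

#' Plugin registry
#'
#' Built-in plugins are registered when the package loads.  Third-party
#' packages extend the registry by calling `register_plugin()` (typically
#' from their `.onLoad()`); ids must be unique.
#'
#' @param descriptor a [plugin_descriptor()].
#' @return `register_plugin()` returns the descriptor invisibly.
#' @export
register_plugin <- function(descriptor) {
  stopifnot(inherits(descriptor, "fsh_plugin"))
  reg <- .fshforge$plugins
  if (!is.null(reg[[descriptor$plugin_id]])) {
    fsh_abort("duplicate-plugin",
              sprintf("a plugin with id '%s' is already registered",
                      descriptor$plugin_id))
  }
  assign(descriptor$plugin_id, descriptor, envir = reg)
  invisible(descriptor)
}

#' @rdname register_plugin
#' @param plugin_id the id to look up (exact match).
#' @return `resolve_plugin()` returns the descriptor; unknown ids raise
#'   `unknown-plugin` listing all registered ids.
#' @export
resolve_plugin <- function(plugin_id) {
  reg <- .fshforge$plugins
  d <- reg[[plugin_id]]
  if (is.null(d)) {
    fsh_abort("unknown-plugin",
              sprintf("no plugin with id '%s'; registered plugins: %s",
                      plugin_id,
                      paste(sort(ls(reg)), collapse = ", ")))
  }
  d
}

#' @rdname register_plugin
#' @export
registered_plugins <- function() {
  sort(ls(.fshforge$plugins))
}

#' Parse a directive argument vector against a plugin's declaration
#'
#' Long and short flags are both accepted, `--flag=value` and
#' `--flag value` forms alike.  Repeatable flags accumulate in order;
#' defaults fill absent optional arguments; mutually exclusive groups
#' enforce at most one given member.
#'
#' @param descriptor a [plugin_descriptor()].
#' @param argv tokenized arguments (see [tokenize_directive()]).
#' @return an object of class `fsh_parsed_args` with `values` (named by
#'   long flag) and `provenance` (`"given"` or `"default"`).
#' @section Errors: `missing-required-argument` (echoes the argument's help
#'   text), `unknown-flag`, `invalid-argument-value`, `mutex-violation`,
#'   `duplicate-flag` (non-repeatable flag given twice).
#' @export
parse_plugin_args <- function(descriptor, argv) {
  specs <- descriptor$arguments
  by_long <- stats::setNames(specs, vapply(specs, `[[`, character(1), "long"))
  short_map <- list()
  for (s in specs) if (!is.null(s$short)) short_map[[s$short]] <- s$long

  values <- list()
  provenance <- character()
  given <- character()

  i <- 1L
  n <- length(argv)
  while (i <= n) {
    tok <- argv[[i]]
    value_inline <- NULL
    if (grepl("^--[a-z][a-z0-9-]*=", tok)) {
      value_inline <- sub("^--[a-z][a-z0-9-]*=", "", tok)
      tok <- sub("=.*$", "", tok)
    }
    long <- if (grepl("^--", tok)) tok else short_map[[tok]] %||% NULL
    if (is.null(long) || is.null(by_long[[long]])) {
      fsh_abort("unknown-flag",
                sprintf("plugin '%s' does not accept '%s' (see its --help)",
                        descriptor$plugin_id, argv[[i]]))
    }
    spec <- by_long[[long]]
    if (spec$kind == "flag") {
      if (!is.null(value_inline)) {
        fsh_abort("invalid-argument-value",
                  sprintf("%s is a switch and takes no value", long))
      }
      val <- TRUE
      i <- i + 1L
    } else {
      if (!is.null(value_inline)) {
        raw <- value_inline
        i <- i + 1L
      } else {
        if (i == n) {
          fsh_abort("invalid-argument-value",
                    sprintf("%s expects a value", long))
        }
        raw <- argv[[i + 1L]]
        i <- i + 2L
      }
      val <- convert_arg_value(spec, raw, descriptor$plugin_id)
    }
    if (long %in% given && !spec$repeatable) {
      fsh_abort("duplicate-flag",
                sprintf("%s may only be given once", long))
    }
    if (spec$repeatable) {
      values[[long]] <- c(values[[long]], list(val))
    } else {
      values[[long]] <- val
    }
    given <- unique(c(given, long))
  }

  # mutex groups: at most one *given* member
  groups <- split(specs, vapply(specs, function(s) s$mutex_group %||% "",
                                character(1)))
  for (g in names(groups)) {
    if (g == "") next
    members <- vapply(groups[[g]], `[[`, character(1), "long")
    hit <- intersect(members, given)
    if (length(hit) > 1L) {
      fsh_abort("mutex-violation",
                sprintf("%s are mutually exclusive; give at most one",
                        paste(hit, collapse = " and ")))
    }
  }

  for (s in specs) {
    if (s$long %in% given) {
      provenance[[s$long]] <- "given"
    } else if (s$required) {
      fsh_abort("missing-required-argument",
                sprintf("plugin '%s' requires %s%s — %s",
                        descriptor$plugin_id, s$long,
                        if (!is.null(s$short)) paste0(" (", s$short, ")") else "",
                        s$help))
    } else if (!is.null(s$default)) {
      values[[s$long]] <- if (s$repeatable) as.list(s$default) else s$default
      provenance[[s$long]] <- "default"
    }
  }

  structure(list(values = values, provenance = provenance),
            class = "fsh_parsed_args")
}

convert_arg_value <- function(spec, raw, plugin_id) {
  switch(spec$kind,
    string = ,
    path = raw,
    integer = {
      if (!grepl("^[+-]?[0-9]+$", raw)) {
        fsh_abort("invalid-argument-value",
                  sprintf("%s expects an integer, got '%s'", spec$long, raw))
      }
      as.integer(raw)
    },
    choice = {
      if (!raw %in% spec$choices) {
        fsh_abort("invalid-argument-value",
                  sprintf("%s must be one of %s, got '%s'", spec$long,
                          paste(spec$choices, collapse = ", "), raw))
      }
      raw
    },
    key_value_pair = {
      eq <- regexpr("=", raw, fixed = TRUE)
      if (eq == -1L || eq == 1L) {
        fsh_abort("invalid-argument-value",
                  sprintf("%s expects NAME=VALUE, got '%s'", spec$long, raw))
      }
      list(name = substr(raw, 1L, eq - 1L),
           value = substr(raw, eq + 1L, nchar(raw)))
    },
    fsh_abort("invalid-argument-value",
              sprintf("unhandled kind for %s", spec$long)))
}

#' Render the generated help of a plugin
#'
#' Deterministic text listing the plugin summary and, in declaration order,
#' each argument's long/short form, kind, required/default status and help
#' text.
#'
#' @param descriptor a [plugin_descriptor()].
#' @return a character scalar.
#' @export
render_plugin_help <- function(descriptor) {
  out <- c(sprintf("%s — %s", descriptor$plugin_id, descriptor$summary),
           sprintf("supported kinds: %s",
                   paste(descriptor$supported_kinds, collapse = ", ")))
  if (length(descriptor$arguments)) {
    out <- c(out, "", "arguments:")
    for (s in descriptor$arguments) {
      flags <- if (is.null(s$short)) s$long else paste(s$long, s$short, sep = ", ")
      kind <- if (s$kind == "choice") {
        sprintf("choice{%s}", paste(s$choices, collapse = "|"))
      } else {
        s$kind
      }
      status <- if (s$required) {
        "required"
      } else if (s$kind == "flag") {
        "switch"
      } else if (!is.null(s$default)) {
        sprintf("default: %s", paste(format(s$default), collapse = ","))
      } else {
        "optional"
      }
      tag <- if (s$repeatable) paste0(kind, ", repeatable") else kind
      out <- c(out,
               sprintf("  %-28s %s (%s; %s)", flags, s$help, tag, status))
    }
  }
  paste(out, collapse = "\n")
}

#' Dispatch content generation to a plugin
#'
#' Checks that the plugin supports the owning item's kind, invokes its
#' content generator and wraps any plugin-raised failure in a `plugin-error`
#' naming the plugin and owner item.
#'
#' @param descriptor a [plugin_descriptor()].
#' @param parsed the [parse_plugin_args()] result.
#' @param meta the owning item's `term_resource_meta` (plugins may consult
#'   declared properties).
#' @param kind the owning item's kind.
#' @param base_dir directory against which relative `--file` paths resolve
#'   (the directive's source-file directory).
#' @return a [content_bundle()] whose kind matches `kind`.
#' @export
generate_content <- function(descriptor, parsed, meta,
                             kind = meta$resource_kind, base_dir = ".") {
  if (!kind %in% descriptor$supported_kinds) {
    fsh_abort("unsupported-kind",
              sprintf("plugin '%s' cannot generate %s content (supported: %s)",
                      descriptor$plugin_id, kind,
                      paste(descriptor$supported_kinds, collapse = ", ")))
  }
  bundle <- tryCatch(
    descriptor$content_fn(parsed, meta, kind, base_dir),
    error = function(e) {
      # compiler conditions (file-missing, ragged-row, ...) pass through
      # with their own codes; only foreign failures are wrapped
      if (inherits(e, "fshforge_error")) {
        stop(e)
      }
      fsh_abort("plugin-error",
                sprintf("plugin '%s' failed for item '%s': %s",
                        descriptor$plugin_id, meta$name,
                        conditionMessage(e)))
    })
  if (!inherits(bundle, "content_bundle") || !identical(bundle$kind, kind)) {
    fsh_abort("plugin-error",
              sprintf("plugin '%s' returned %s content for a %s item",
                      descriptor$plugin_id,
                      if (inherits(bundle, "content_bundle")) bundle$kind
                      else class(bundle)[[1L]],
                      kind))
  }
  bundle
}
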