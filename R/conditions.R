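# Condition machinery.  Every compile-time failure is signalled as a classed
# condition carrying a stable machine code (kebab-case), an optional 1-based
# source line/column, and arbitrary data fields.  The app module catches
# these per item and converts them into issues (see validate.R).

fsh_abort <- function(code, message, line = NULL, column = NULL, ...) {
  cls <- c(paste0("fshforge_", gsub("-", "_", code, fixed = TRUE)),
           "fshforge_error", "error", "condition")
  cond <- structure(
    class = cls,
    list(message = message, call = NULL, code = code,
         line = line, column = column, ...)
  )
  stop(cond)
}

# Accumulated-parse-error condition: `errors` is a list of records with
# fields code/message/line/column.
fsh_abort_parse <- function(errors, source_path) {
  n <- length(errors)
  first <- errors[[1L]]
  msg <- sprintf("%s:%s: %s%s", source_path, first$line, first$message,
                 if (n > 1L) sprintf(" (and %d more error%s)", n - 1L,
                                     if (n > 2L) "s" else "") else "")
  cond <- structure(
    class = c("fshforge_syntax_error", "fshforge_parse_error",
              "fshforge_error", "error", "condition"),
    list(message = msg, call = NULL, code = "syntax-error",
         errors = errors, source_path = source_path,
         line = first$line, column = first$column)
  )
  stop(cond)
}

parse_error_record <- function(code, message, line, column = NULL) {
  list(code = code, message = message, line = line, column = column)
}

# --- logging ---------------------------------------------------------------

.log_levels <- c(debug = 10L, info = 20L, warning = 30L, error = 40L)

fsh_log <- function(level, fmt, ...) {
  threshold <- getOption("fshforge.log_level", "warning")
  if (.log_levels[[level]] < .log_levels[[threshold]]) {
    return(invisible())
  }
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  cat(sprintf("[%s] %s\n", toupper(level), msg), file = stderr(), sep = "")
  invisible()
}
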