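#' Canonical JSON trees
#'
#' The compiler and its test oracle share one canonical JSON writer so that
#' equality of outputs can be asserted on bytes.  A JSON tree is an ordinary
#' R structure: a named list is an object (members that are `NULL` are
#' dropped), a list tagged with [json_array()] is an array, a length-1
#' character/logical/integer is the corresponding scalar.  Decimal literals
#' are carried verbatim as character vectors of class `json_number` so that
#' `1.10` survives round trips untouched.
#'
#' @param x a list to be serialized as a JSON array.
#' @return `json_array()` returns its input with class `json_array`.
#' @examples
#' write_canonical_json(list(resourceType = "CodeSystem", count = 2L))
#' @export
json_array <- function(x = list()) {
  stopifnot(is.list(x))
  structure(x, class = "json_array")
}

#' @rdname json_array
#' @param text a character scalar holding a JSON number literal.
#' @export
json_number <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  structure(text, class = "json_number")
}

#' @rdname json_array
#' @param tree a JSON tree (see Details).
#' @param path optional file path; when given the rendered bytes are written
#'   (UTF-8, LF line endings, trailing newline) and the path is returned
#'   invisibly.
#' @return `write_canonical_json()` returns the rendered JSON as a UTF-8
#'   character scalar, or the path when `path` is given.
#' @export
write_canonical_json <- function(tree, path = NULL) {
  txt <- .json_emit(tree)
  if (is.null(path)) {
    return(txt)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(txt)), con)
  invisible(path)
}
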