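#' Extract content-generation directives from source text
#'
#' Directives are block comments whose opener is the recognition token
#' `/*^babelfsh` (no space after `/*`, matched case-sensitively) and whose
#' closer is `^babelfsh*/`.  Ordinary `/* ... */` comments are ignored, so
#' normal comments are never hijacked.  Regions may span multiple lines and
#' are returned in document order.
#'
#' @param text source characters: a single string or a character vector of
#'   lines (joined with `"\n"`).
#' @return a list of directive regions, each a list with `start_line`,
#'   `end_line`, `start_offset`, `end_offset` (1-based character offsets of
#'   the full region including the tokens) and `raw_body` (the characters
#'   between the tokens).
#' @seealso [tokenize_directive()]
#' @export
extract_directives <- function(text) {
  text <- paste(text, collapse = "\n")
  open_tok <- "/*^babelfsh"
  close_tok <- "^babelfsh*/"
  nc <- nchar(text, type = "chars")
  regions <- list()
  pos <- 1L
  repeat {
    rest <- substr(text, pos, nc)
    hit <- regexpr(open_tok, rest, fixed = TRUE)
    if (hit == -1L) break
    start <- pos + as.integer(hit) - 1L
    body_start <- start + nchar(open_tok)
    rest2 <- substr(text, body_start, nc)
    closer <- regexpr(close_tok, rest2, fixed = TRUE)
    if (closer == -1L) {
      fsh_abort("unterminated-directive",
                sprintf("directive opened at line %d is never closed with '%s'",
                        line_of_offset(text, start), close_tok),
                line = line_of_offset(text, start))
    }
    body_end <- body_start + as.integer(closer) - 2L
    end <- body_end + nchar(close_tok)
    regions[[length(regions) + 1L]] <- list(
      start_line = line_of_offset(text, start),
      end_line = line_of_offset(text, end),
      start_offset = start,
      end_offset = end,
      raw_body = substr(text, body_start, body_end)
    )
    pos <- end + 1L
  }
  regions
}

line_of_offset <- function(text, offset) {
  if (offset <= 1L) {
    return(1L)
  }
  prefix <- substr(text, 1L, offset - 1L)
  1L + nchar(gsub("[^\n]", "", prefix))
}

#' Tokenize a directive body into plugin id and argument vector
#'
#' Tokenization is shell-like: tokens are separated by whitespace (newlines
#' included), double quotes group tokens containing spaces or delimiter
#' characters, and a backslash escapes the next character.  The first token
#' is the plugin id; the rest form the argument vector.
#'
#' @param raw_body the characters between the directive tokens.
#' @return a list with `plugin_id` (string) and `argv` (character vector).
#' @export
tokenize_directive <- function(raw_body) {
  tokens <- shell_tokenize(raw_body)
  if (length(tokens) == 0L) {
    fsh_abort("empty-directive", "directive contains no tokens")
  }
  list(plugin_id = tokens[[1L]], argv = tokens[-1L])
}

shell_tokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  tokens <- character()
  cur <- character()
  have_cur <- FALSE
  in_quote <- FALSE
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "\\") {
      if (i == n) {
        fsh_abort("unbalanced-quote", "dangling backslash at end of directive")
      }
      cur <- c(cur, chars[[i + 1L]])
      have_cur <- TRUE
      i <- i + 2L
      next
    }
    if (ch == "\"") {
      in_quote <- !in_quote
      have_cur <- TRUE # empty quoted string is a token
      i <- i + 1L
      next
    }
    if (!in_quote && grepl("^[ \t\r\n]$", ch)) {
      if (have_cur) {
        tokens <- c(tokens, paste(cur, collapse = ""))
        cur <- character()
        have_cur <- FALSE
      }
      i <- i + 1L
      next
    }
    cur <- c(cur, ch)
    have_cur <- TRUE
    i <- i + 1L
  }
  if (in_quote) {
    fsh_abort("unbalanced-quote", "unterminated double quote in directive")
  }
  if (have_cur) {
    tokens <- c(tokens, paste(cur, collapse = ""))
  }
  tokens
}
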