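# Shared test fixtures, built in code.

# Standard metadata header used by compile tests; `directive` is pasted in
# verbatim below the rules.
demo_cs_source <- function(directive,
                           name = "DemoCS", id = "demo-cs",
                           rules = character()) {
  c(sprintf("CodeSystem: %s", name),
    sprintf("Id: %s", id),
    'Title: "Demo code system"',
    'Description: "A synthetic demonstration code system."',
    '* ^url = "http://example.org/fhir/CodeSystem/demo"',
    '* ^version = "2025"',
    '* ^status = #active',
    '* ^experimental = false',
    '* ^date = "2025-01-01"',
    '* ^publisher = "Example Org"',
    '* ^caseSensitive = true',
    '* ^content = #complete',
    rules,
    directive)
}

# matching plain-R metadata for the brute-force oracle
demo_cs_meta <- function() {
  list(id = "demo-cs", url = "http://example.org/fhir/CodeSystem/demo",
       version = "2025", name = "DemoCS", title = "Demo code system",
       status = "active", experimental = FALSE, date = "2025-01-01",
       publisher = "Example Org",
       description = "A synthetic demonstration code system.",
       caseSensitive = TRUE, content = "complete")
}

hierarchy_csv_directive <- function(file = "t.csv", extra = "") {
  sprintf("/*^babelfsh delimited-table --file %s --display-column DISPLAY --inactive-column INACTIVE --parent-column PARENT%s ^babelfsh*/",
          file, if (nzchar(extra)) paste0(" ", extra) else "")
}

hierarchy_csv_mapping <- function() {
  list(delimiter = ",", has_header = TRUE, code = 1L, display = 2L,
       inactive = 3L, parent = 4L,
       true_values = c("YES", "Y", "TRUE", "1"))
}

# compile one directory, return the result
compile_dir <- function(dir, mode = "r4b", ...) {
  fsh_compile(dir, mode, out_dir = file.path(dir, "out"), ...)
}

issue_codes <- function(res) {
  vapply(res$issues, `[[`, character(1), "code")
}

issue_lines <- function(res) {
  vapply(res$issues, `[[`, integer(1), "line")
}

# a scratch project directory with a table and one FSH source
make_project <- function(src_lines, table_lines = NULL,
                         table_file = "t.csv",
                         src_file = "main.babel.fsh") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  if (!is.null(table_lines)) {
    writeLines(table_lines, file.path(dir, table_file))
  }
  writeLines(src_lines, file.path(dir, src_file))
  dir
}

# remove every directive region from source text (used by the
# comment-neutrality tests); deletion by character offsets
strip_directives <- function(text) {
  text <- paste(text, collapse = "\n")
  regions <- extract_directives(text)
  for (r in rev(regions)) {
    text <- paste0(substr(text, 1L, r$start_offset - 1L),
                   substr(text, r$end_offset + 1L, nchar(text)))
  }
  text
}

# structural view of a parse result with directives ignored
parse_fingerprint <- function(doc) {
  list(aliases = doc$aliases,
       rulesets = doc$rulesets,
       items = lapply(doc$items, function(it) {
         it$directives <- NULL
         it
       }))
}
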