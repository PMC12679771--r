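test_that("pipe tables parse with verbatim cells and skipped lines", {
  f <- withr::local_tempfile(lines = c(
    "# a comment",
    "CODE|DISPLAY|X",
    "A| padded |1",
    "",
    "B|two|2",
    "C|three|"))
  t <- read_delimited_table(f, delimiter = "|", comment_prefix = "#")
  expect_identical(t$header, c("CODE", "DISPLAY", "X"))
  expect_identical(nrow(t$cells), 3L)
  expect_identical(t$cells[1L, 2L], " padded ")   # no trimming
  expect_identical(t$cells[3L, 3L], "")           # trailing empty cell kept
  expect_identical(t$lines, c(3L, 5L, 6L))
})

test_that("ragged rows report their 1-based line number", {
  f <- withr::local_tempfile(lines = c("CODE|D", "A|a", "B"))
  err <- tryCatch(read_delimited_table(f, delimiter = "|"),
                  fshforge_error = function(e) e)
  expect_identical(err$code, "ragged-row")
  expect_identical(err$line, 3L)
  expect_error(read_delimited_table(tempfile(), delimiter = "|"),
               class = "fshforge_file_missing")
})

test_that("CRLF and LF files yield identical records", {
  lf <- withr::local_tempfile()
  crlf <- withr::local_tempfile()
  writeBin(charToRaw("CODE,D\nA,a\nB,b\n"), lf)
  writeBin(charToRaw("CODE,D\r\nA,a\r\nB,b\r\n"), crlf)
  expect_identical(read_delimited_table(lf)$cells,
                   read_delimited_table(crlf)$cells)
})

test_that("RFC-4180 quoting is honored for comma tables only", {
  f <- withr::local_tempfile(lines = c(
    'CODE,DISPLAY',
    'A,"with, comma"',
    'B,"escaped ""quote"""'))
  t <- read_delimited_table(f)
  expect_identical(t$cells[, 2L], c("with, comma", 'escaped "quote"'))
  # pipe files are raw splits: quotes stay verbatim
  f2 <- withr::local_tempfile(lines = c("CODE|DISPLAY", 'A|"kept"'))
  expect_identical(read_delimited_table(f2, delimiter = "|")$cells[1L, 2L],
                   '"kept"')
})

test_that("latin1 re-encodes and invalid UTF-8 reports a byte offset", {
  f <- withr::local_tempfile()
  writeBin(c(charToRaw("CODE,D\nA,"), as.raw(0xE4), charToRaw("\n")), f)
  t <- read_delimited_table(f, encoding = "latin1")
  expect_identical(t$cells[1L, 2L], "ä")
  err <- tryCatch(read_delimited_table(f, encoding = "utf-8"),
                  fshforge_error = function(e) e)
  expect_identical(err$code, "decode-error")
  expect_match(conditionMessage(err), "offset")
})

fig1_table <- function() {
  list(header = c("CODE", "DISPLAY", "PARENT", "INACTIVE"),
       cells = matrix(c("A", "Root", "", "NO",
                        "B", "Leaf", "A", "NO",
                        "C", "Old leaf", "A", "YES"),
                      ncol = 4L, byrow = TRUE),
       lines = 2:4, width = 4L)
}

base_mapping <- function(...) {
  m <- list(code = 1L, display = 2L, definition = NA_integer_,
            parent = 3L, inactive = 4L,
            true_values = c("YES", "Y", "TRUE", "1"),
            hierarchy = "parent", allow_dangling = FALSE,
            property_mappings = list())
  override <- list(...)
  m[names(override)] <- override
  m
}

prop_str <- function(concept) {
  vapply(concept$properties, function(p) {
    paste0(p$code, "=", p$value)
  }, character(1))
}

test_that("code/display/parent/inactive columns map onto concepts", {
  res <- rows_to_concepts(fig1_table(), base_mapping())
  expect_length(res$concepts, 3L)
  expect_identical(vapply(res$concepts, `[[`, character(1), "code"),
                   c("A", "B", "C"))
  expect_length(res$concepts[[1L]]$properties, 0L)
  expect_identical(prop_str(res$concepts[[2L]]), "parent=A")
  expect_identical(prop_str(res$concepts[[3L]]),
                   c("inactive=TRUE", "parent=A"))
})

test_that("rows sharing a code merge into one concept in row order", {
  t <- list(header = c("CODE", "DISPLAY", "P1"),
            cells = matrix(c("Z", "Same", "x",
                             "Z", "Same", "y"), ncol = 3L, byrow = TRUE),
            lines = 2:3, width = 3L)
  m <- base_mapping(display = 2L, parent = NA_integer_,
                    inactive = NA_integer_,
                    property_mappings = list(
                      list(code = "p1", col = 3L, type = "string")))
  res <- rows_to_concepts(t, m, declared = list(p1 = "string"))
  expect_length(res$concepts, 1L)
  expect_identical(prop_str(res$concepts[[1L]]), c("p1=x", "p1=y"))
})

test_that("merge conflicts, empty codes and bad cells are positioned errors", {
  t <- fig1_table()
  t$cells[3L, ] <- c("A", "Different", "", "NO")
  err <- tryCatch(rows_to_concepts(t, base_mapping()),
                  fshforge_error = function(e) e)
  expect_identical(err$code, "duplicate-code-conflict")
  expect_identical(err$line, 4L)

  t <- fig1_table()
  t$cells[2L, 1L] <- ""
  err <- tryCatch(rows_to_concepts(t, base_mapping()),
                  fshforge_error = function(e) e)
  expect_identical(err$code, "empty-code")
  expect_identical(err$line, 3L)

  t <- fig1_table()
  t$cells[2L, 3L] <- "NOPE"
  err <- tryCatch(rows_to_concepts(t, base_mapping()),
                  fshforge_error = function(e) e)
  expect_identical(err$code, "dangling-parent")
  expect_identical(err$line, 3L)
  res <- rows_to_concepts(t, base_mapping(allow_dangling = TRUE))
  expect_identical(res$dangling, "NOPE")
  expect_identical(prop_str(res$concepts[[2L]]), "parent=NOPE")

  m <- base_mapping(property_mappings = list(
    list(code = "undeclared", col = 2L, type = "string")))
  err <- tryCatch(rows_to_concepts(fig1_table(), m),
                  fshforge_error = function(e) e)
  expect_identical(err$code, "undeclared-property")

  t <- fig1_table()
  m <- base_mapping(property_mappings = list(
    list(code = "rank", col = 2L, type = "integer")))
  err <- tryCatch(rows_to_concepts(t, m, declared = list(rank = "integer")),
                  fshforge_error = function(e) e)
  expect_identical(err$code, "invalid-property-value")
  expect_identical(err$line, 2L)
})

test_that("hierarchy modes emit the configured representation", {
  child <- rows_to_concepts(fig1_table(), base_mapping(hierarchy = "child"))
  expect_identical(prop_str(child$concepts[[1L]]), c("child=B", "child=C"))
  expect_length(child$concepts[[2L]]$properties, 0L)

  both <- rows_to_concepts(fig1_table(), base_mapping(hierarchy = "both"))
  expect_identical(prop_str(both$concepts[[1L]]), c("child=B", "child=C"))
  expect_identical(prop_str(both$concepts[[2L]]), "parent=A")

  nested <- rows_to_concepts(fig1_table(), base_mapping(hierarchy = "nested"))
  expect_length(nested$concepts, 1L)
  expect_identical(vapply(nested$concepts[[1L]]$children, `[[`,
                          character(1), "code"), c("B", "C"))

  m <- base_mapping(hierarchy = "nested", property_mappings = list(
    list(code = "parent", col = 3L, type = "code")))
  expect_error(rows_to_concepts(fig1_table(), m),
               class = "fshforge_concurrent_hierarchy")
})

test_that("counts are conserved on generated fixtures", {
  for (seed in c(3L, 11L, 27L)) {
    f <- withr::local_tempfile()
    manifest <- generate_table(
      fixture_spec(40, seed = seed, duplicate_code_fraction = 0.15), f)
    t <- read_delimited_table(f)
    m <- base_mapping(parent = 4L, inactive = 3L)
    res <- rows_to_concepts(t, m)
    expect_length(res$concepts, manifest$expected_concepts)
    n_props <- sum(vapply(res$concepts, function(c) length(c$properties),
                          integer(1)))
    expect_identical(n_props,
                     manifest$expected_parent_properties +
                       manifest$expected_inactive_properties)
  }
})

test_that("row count scales without blowing up runtime", {
  time_rows <- function(n) {
    f <- withr::local_tempfile()
    generate_table(fixture_spec(n, seed = 2, layout = "alpha_like"), f)
    m <- list(code = 2L, display = 7L, definition = NA_integer_,
              parent = NA_integer_, inactive = 1L, true_values = "0",
              hierarchy = "parent", allow_dangling = FALSE,
              property_mappings = list(
                list(code = "primary-code", col = 3L, type = "code")))
    t0 <- proc.time()[["elapsed"]]
    res <- rows_to_concepts(read_delimited_table(f, delimiter = "|",
                                                 has_header = FALSE),
                            m, declared = list(`primary-code` = "code"))
    expect_length(res$concepts, n)
    proc.time()[["elapsed"]] - t0
  }
  small <- time_rows(10000L)
  large <- time_rows(100000L)
  expect_lt(large, 20 * max(small, 0.05))
})
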