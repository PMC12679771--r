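test_that("source discovery filters by extension and sorts", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "sub"))
  for (f in c("b.babelfsh.fsh", "a.babel.fsh", "c.fsh", "sub/d.babel.fsh")) {
    writeLines("CodeSystem: X", file.path(dir, f))
  }
  got <- discover_sources(dir)
  expect_identical(basename(got), c("a.babel.fsh", "b.babelfsh.fsh",
                                    "d.babel.fsh"))
  err <- tryCatch(discover_sources(file.path(dir, "c.fsh")),
                  fshforge_error = function(e) e)
  expect_identical(err$code, "path-missing")
  expect_match(conditionMessage(err), "extension")
  expect_error(discover_sources(file.path(dir, "nope")),
               class = "fshforge_path_missing")
  empty <- withr::local_tempdir()
  expect_error(discover_sources(empty), class = "fshforge_no_sources")
})

test_that("a 33-concept source compiles to one CodeSystem with 33 concepts", {
  dir <- withr::local_tempdir()
  generate_table(fixture_spec(33, seed = 42), file.path(dir, "t.csv"))
  writeLines(demo_cs_source(hierarchy_csv_directive()),
             file.path(dir, "demo.babel.fsh"))
  res <- compile_dir(dir)
  expect_true(res$ok)
  expect_length(res$written, 1L)
  expect_identical(basename(res$written), "CodeSystem-demo-cs.json")
  j <- jsonlite::fromJSON(res$written, simplifyVector = FALSE)
  expect_length(j$concept, 33L)
  expect_identical(j$count, 33L)
})

test_that("items without exactly one directive fail; siblings are isolated", {
  dir <- withr::local_tempdir()
  generate_table(fixture_spec(5, seed = 1), file.path(dir, "t.csv"))
  writeLines(c("CodeSystem: NoDirective",
               "Id: no-directive",
               '* ^url = "http://example.org/none"',
               "* ^status = #active",
               demo_cs_source(hierarchy_csv_directive())),
             file.path(dir, "two.babel.fsh"))
  res <- compile_dir(dir)
  expect_false(res$ok)
  expect_identical(issue_codes(res), "missing-directive")
  expect_identical(issue_lines(res), 1L)
  expect_length(res$written, 1L)   # the healthy sibling still compiled

  # removing the failing item does not change the sibling's output
  sibling_bytes <- readChar(res$written, file.size(res$written))
  dir2 <- withr::local_tempdir()
  generate_table(fixture_spec(5, seed = 1), file.path(dir2, "t.csv"))
  writeLines(demo_cs_source(hierarchy_csv_directive()),
             file.path(dir2, "solo.babel.fsh"))
  res2 <- compile_dir(dir2)
  expect_identical(readChar(res2$written, file.size(res2$written)),
                   sibling_bytes)

  dir3 <- withr::local_tempdir()
  generate_table(fixture_spec(5, seed = 1), file.path(dir3, "t.csv"))
  writeLines(c(demo_cs_source(hierarchy_csv_directive()),
               "/*^babelfsh delimited-table --file t.csv ^babelfsh*/"),
             file.path(dir3, "multi.babel.fsh"))
  res3 <- compile_dir(dir3)
  expect_identical(issue_codes(res3), "multiple-directives")
})

test_that("two invocations on an identical tree are byte-identical", {
  make <- function() {
    dir <- withr::local_tempdir(.local_envir = parent.frame())
    generate_table(fixture_spec(20, seed = 9), file.path(dir, "t.csv"))
    writeLines(demo_cs_source(hierarchy_csv_directive()),
               file.path(dir, "demo.babel.fsh"))
    res <- compile_dir(dir)
    expect_true(res$ok)
    readBin(res$written, "raw", file.size(res$written))
  }
  expect_identical(make(), make())
})

test_that("RuleSets resolve project-wide across files, duplicates rejected", {
  dir <- withr::local_tempdir()
  generate_table(fixture_spec(5, seed = 3), file.path(dir, "t.csv"))
  writeLines(c("RuleSet: shared-meta(ver)",
               '* ^version = "{ver}"',
               "* ^status = #active"),
             file.path(dir, "a-rulesets.babel.fsh"))
  writeLines(c("CodeSystem: Uses",
               "Id: uses",
               '* ^url = "http://example.org/uses"',
               "* insert shared-meta(3.1)",
               hierarchy_csv_directive()),
             file.path(dir, "b-item.babel.fsh"))
  res <- compile_dir(dir)
  expect_true(res$ok)
  j <- jsonlite::fromJSON(res$written, simplifyVector = FALSE)
  expect_identical(j$version, "3.1")

  writeLines(c("RuleSet: shared-meta(ver)", '* ^version = "{ver}"'),
             file.path(dir, "c-dup.babel.fsh"))
  res <- compile_dir(dir)
  expect_true("duplicate-ruleset" %in% issue_codes(res))
})

test_that("relative --file paths resolve against the source file directory", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "nested"))
  generate_table(fixture_spec(4, seed = 2),
                 file.path(dir, "nested", "t.csv"))
  writeLines(demo_cs_source(hierarchy_csv_directive()),
             file.path(dir, "nested", "demo.babel.fsh"))
  withr::local_dir(tempdir())  # working directory is elsewhere
  res <- fsh_compile(dir, "r4b", out_dir = file.path(dir, "out"))
  expect_true(res$ok)
})

test_that("a --help directive prints plugin help and skips the item", {
  dir <- withr::local_tempdir()
  writeLines(demo_cs_source("/*^babelfsh delimited-table --help ^babelfsh*/"),
             file.path(dir, "demo.babel.fsh"))
  out <- capture.output(res <- compile_dir(dir), type = "message")
  expect_true(res$ok)
  expect_length(res$written, 0L)
  expect_identical(issue_codes(res), "help-requested")
  expect_match(paste(out, collapse = "\n"), "--file, -f", fixed = TRUE)
})

test_that("exit codes: 0 clean, 1 compile errors, 2 usage errors", {
  dir <- withr::local_tempdir()
  generate_table(fixture_spec(6, seed = 4), file.path(dir, "t.csv"))
  writeLines(demo_cs_source(hierarchy_csv_directive()),
             file.path(dir, "demo.babel.fsh"))
  out <- file.path(dir, "out")
  suppressMessages({
    expect_identical(
      fshforge_main(c("compile", "--fhir-version", "r4b", "--out", out, dir)),
      0L)
    expect_identical(
      fshforge_main(c("compile", "--fhir-version", "r4b", "--bogus", "x",
                      dir)),
      2L)
    expect_identical(fshforge_main(c("compile", dir)), 2L)
    expect_identical(fshforge_main("frobnicate"), 2L)
  })

  # dangling parent at default severity exits 1
  dir2 <- withr::local_tempdir()
  writeLines(c("CODE,DISPLAY,INACTIVE,PARENT", "A,Root,NO,ZZZ"),
             file.path(dir2, "t.csv"))
  writeLines(demo_cs_source(hierarchy_csv_directive()),
             file.path(dir2, "demo.babel.fsh"))
  suppressMessages(code <- fshforge_main(
    c("compile", "--fhir-version", "r4b", "--out", file.path(dir2, "out"),
      dir2)))
  expect_identical(code, 1L)
})

test_that("the deep-validation hook relays failures as warnings only", {
  dir <- withr::local_tempdir()
  generate_table(fixture_spec(3, seed = 8), file.path(dir, "t.csv"))
  writeLines(demo_cs_source(hierarchy_csv_directive()),
             file.path(dir, "demo.babel.fsh"))
  res <- fsh_compile(dir, "r4b", out_dir = file.path(dir, "out"),
                     deep_validate = "false")  # POSIX `false`: exit 1
  expect_true(res$ok)   # warnings never block output
  expect_identical(issue_codes(res), "deep-validation")
  expect_identical(res$issues[[1L]]$severity, "warning")
})
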