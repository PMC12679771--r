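test_that("a minimal well-formed item parses", {
  doc <- fsh_parse(c("CodeSystem: Demo",
                     "Id: demo",
                     '* ^url = "http://example.org/cs"'))
  expect_length(doc$items, 1L)
  it <- doc$items[[1L]]
  expect_identical(it$kind, "codesystem")
  expect_identical(it$name, "Demo")
  expect_identical(it$keyword_meta[["Id"]], "demo")
  expect_identical(it$decl_line, 1L)
  expect_length(it$rules, 1L)
  expect_identical(it$rules[[1L]]$variant, "caret_value")
  expect_identical(it$rules[[1L]]$path, "url")
  expect_identical(it$rules[[1L]]$value$parsed, "http://example.org/cs")
  expect_identical(doc$line_count, 3L)
})

test_that("ordinary comments are discarded, never hijacked as directives", {
  doc <- fsh_parse(c("/* a note */",
                     "CodeSystem: Demo // trailing comment",
                     "Id: demo /* inline */",
                     '* ^url = "http://example.org/cs"'))
  expect_length(doc$items, 1L)
  expect_length(doc$items[[1L]]$directives, 0L)
  expect_identical(doc$items[[1L]]$keyword_meta[["Id"]], "demo")
})

test_that("syntax errors carry 1-based lines inside the file range", {
  src <- c("CodeSystem: Demo",
           "Id: demo",
           "",
           "* ^url \"missing equals\"")
  err <- tryCatch(fsh_parse(src), fshforge_parse_error = function(e) e)
  expect_s3_class(err, "fshforge_parse_error")
  expect_identical(err$errors[[1L]]$line, 4L)
  for (e in err$errors) {
    expect_gte(e$line, 1L)
    expect_lte(e$line, length(src))
  }
})

test_that("aliases resolve in code and canonical positions", {
  doc <- fsh_parse(c("Alias: $cp = http://example.org/props",
                     "CodeSystem: Demo",
                     "* ^property[0].uri = $cp",
                     "* ^url = $cp"))
  vals <- lapply(doc$items[[1L]]$rules, function(r) r$value$parsed)
  expect_identical(vals[[1L]], "http://example.org/props")
  expect_identical(vals[[2L]], "http://example.org/props")

  err <- tryCatch(fsh_parse(c("CodeSystem: D", "* ^url = $nope")),
                  fshforge_parse_error = function(e) e)
  expect_identical(err$errors[[1L]]$code, "unknown-alias")
})

test_that("multiline strings trim the minimal common indent", {
  doc <- fsh_parse(c("CodeSystem: Demo",
                     'Description: """',
                     "    First line",
                     "      indented more",
                     "    back",
                     '    """'))
  expect_identical(doc$items[[1L]]$keyword_meta[["Description"]],
                   "First line\n  indented more\nback")
})

test_that("inline concept and value-set content rules are hard errors", {
  err <- tryCatch(fsh_parse(c("CodeSystem: D", '* #a "Display A"')),
                  fshforge_parse_error = function(e) e)
  expect_identical(err$errors[[1L]]$code, "inline-concept")
  expect_match(err$errors[[1L]]$message, "plugin")

  err <- tryCatch(
    fsh_parse(c("ValueSet: V", "* include codes from system http://x")),
    fshforge_parse_error = function(e) e)
  expect_identical(err$errors[[1L]]$code, "inline-content")
})

test_that("unsupported FSH constructs are rejected with targeted messages", {
  err <- tryCatch(fsh_parse(c("Profile: P", "Parent: Patient")),
                  fshforge_parse_error = function(e) e)
  expect_identical(err$errors[[1L]]$code, "unsupported-keyword")

  err <- tryCatch(fsh_parse(c("Instance: M", "InstanceOf: Patient")),
                  fshforge_parse_error = function(e) e)
  expect_identical(err$errors[[1L]]$code, "unsupported-keyword")

  err <- tryCatch(fsh_parse(c("CodeSystem: D", "Id: a", "Id: b")),
                  fshforge_parse_error = function(e) e)
  expect_identical(err$errors[[1L]]$code, "duplicate-keyword")
})

test_that("instance items require InstanceOf ConceptMap", {
  doc <- fsh_parse(c("Instance: Map",
                     "InstanceOf: ConceptMap",
                     "Usage: #definition",
                     '* url = "http://example.org/cm"'))
  it <- doc$items[[1L]]
  expect_identical(it$kind, "instance")
  expect_identical(it$instance_of, "ConceptMap")
  expect_identical(it$rules[[1L]]$variant, "plain_assignment")

  err <- tryCatch(fsh_parse("Instance: M"),
                  fshforge_parse_error = function(e) e)
  expect_match(err$errors[[1L]]$message, "InstanceOf")
})

test_that("caret rules and plain assignments are gated by item kind", {
  err <- tryCatch(
    fsh_parse(c("Instance: M", "InstanceOf: ConceptMap",
                '* ^url = "http://x"')),
    fshforge_parse_error = function(e) e)
  expect_match(err$errors[[1L]]$message, "caret")

  err <- tryCatch(fsh_parse(c("CodeSystem: D", '* url = "http://x"')),
                  fshforge_parse_error = function(e) e)
  expect_match(err$errors[[1L]]$message, "plain assignment")
})

test_that("directives attach to the lexically enclosing item", {
  doc <- fsh_parse(c("CodeSystem: A",
                     "/*^babelfsh p1 --x 1 ^babelfsh*/",
                     "CodeSystem: B",
                     "/*^babelfsh p2 ^babelfsh*/"))
  expect_identical(doc$items[[1L]]$directives[[1L]]$plugin_id, "p1")
  expect_identical(doc$items[[1L]]$directives[[1L]]$owner_item, "A")
  expect_identical(doc$items[[2L]]$directives[[1L]]$plugin_id, "p2")
  expect_length(doc$orphan_directives, 0L)

  doc <- fsh_parse(c("/*^babelfsh early ^babelfsh*/", "CodeSystem: A"))
  expect_length(doc$orphan_directives, 1L)
  expect_length(doc$items[[1L]]$directives, 0L)
})

test_that("duplicate names for items, aliases and RuleSets are rejected", {
  err <- tryCatch(fsh_parse(c("CodeSystem: A", "CodeSystem: A")),
                  fshforge_parse_error = function(e) e)
  expect_identical(err$errors[[1L]]$code, "duplicate-name")

  err <- tryCatch(fsh_parse(c("Alias: $a = http://x", "Alias: $a = http://y")),
                  fshforge_parse_error = function(e) e)
  expect_identical(err$errors[[1L]]$code, "duplicate-name")

  err <- tryCatch(fsh_parse(c("RuleSet: r", '* ^version = "1"',
                              "RuleSet: r", '* ^version = "2"')),
                  fshforge_parse_error = function(e) e)
  expect_identical(err$errors[[1L]]$code, "duplicate-name")
})

test_that("parse -> expand -> interpret is deterministic on the same bytes", {
  src <- c("Alias: $cs = http://example.org/cs",
           "RuleSet: meta(ver)",
           '* ^version = "{ver}"',
           "CodeSystem: Demo",
           "Id: demo",
           "* ^url = $cs",
           "* insert meta(2025)",
           "* ^status = #active")
  one <- fsh_interpret_metadata(
    fsh_expand_rulesets(fsh_parse(src))$items[[1L]], "R4B")
  two <- fsh_interpret_metadata(
    fsh_expand_rulesets(fsh_parse(src))$items[[1L]], "R4B")
  expect_identical(one, two)
  expect_identical(one$version, "2025")
})
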