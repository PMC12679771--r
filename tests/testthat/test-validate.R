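validated_cs <- function(concepts, rules = character(),
                         allow_dangling = FALSE, mode = "R4B") {
  doc <- fsh_parse(c("CodeSystem: DemoCS", "Id: demo",
                     '* ^url = "http://example.org/cs"',
                     "* ^status = #active", rules))
  meta <- fsh_interpret_metadata(doc$items[[1L]], mode)
  r <- assemble_resource(meta, content_bundle("codesystem", concepts), mode)
  validate_structure(r, mode, allow_dangling_parents = allow_dangling)
}

codes_of <- function(issues) vapply(issues, `[[`, character(1), "code")

test_that("duplicate concept codes are errors naming the code", {
  found <- validated_cs(list(concept_entry("A"), concept_entry("A")))
  expect_identical(codes_of(found), "duplicate-code")
  expect_match(found[[1L]]$message, "'A'")
})

test_that("dangling hierarchy references are errors, downgradable", {
  cs <- list(concept_entry("B", properties = list(
    concept_property("parent", "Z", "code"))))
  found <- validated_cs(cs)
  expect_identical(codes_of(found), "dangling-parent")
  expect_identical(found[[1L]]$severity, "error")
  found <- validated_cs(cs, allow_dangling = TRUE)
  expect_identical(found[[1L]]$severity, "warning")
})

test_that("nested children plus parent/child properties is a warning", {
  cs <- list(concept_entry("A", children = list(concept_entry("A1"))),
             concept_entry("B", properties = list(
               concept_property("parent", "A", "code"))))
  found <- validated_cs(cs)
  expect_identical(codes_of(found), "concurrent-hierarchy")
  expect_identical(found[[1L]]$severity, "warning")
})

test_that("missing status, bad urls, names and displays are flagged", {
  doc <- fsh_parse(c("CodeSystem: lowercase_name",
                     '* ^url = "not a url"'))
  meta <- fsh_interpret_metadata(doc$items[[1L]], "R4B")
  r <- assemble_resource(meta, content_bundle("codesystem", list(
    concept_entry("A", display = ""))), "R4B")
  found <- validate_structure(r, "R4B")
  expect_setequal(codes_of(found),
                  c("missing-status", "invalid-url", "name-convention",
                    "empty-display"))
  sev <- vapply(found, `[[`, character(1), "severity")
  expect_identical(sort(unique(sev[codes_of(found) %in%
                                     c("missing-status", "invalid-url")])),
                   "error")
})

has_errors_public <- function(issues) {
  any(vapply(issues, function(i) i$severity %in% c("fatal", "error"),
             logical(1)))
}

test_that("a resource with zero errors always serializes", {
  for (case in list(list(concept_entry("A")),
                    list(concept_entry("B", display = "b", properties = list(
                      concept_property("inactive", TRUE, "boolean")))))) {
    found <- validated_cs(case)
    expect_false(has_errors_public(found))
    doc <- fsh_parse(c("CodeSystem: DemoCS", "Id: demo",
                       '* ^url = "http://example.org/cs"',
                       "* ^status = #active"))
    meta <- fsh_interpret_metadata(doc$items[[1L]], "R4B")
    r <- assemble_resource(meta, content_bundle("codesystem", case), "R4B")
    expect_no_error(serialize_fhir(r, "R4B"))
  }
})

test_that("validation is deterministic with stable issue order", {
  cs <- list(concept_entry("A"), concept_entry("A"),
             concept_entry("B", display = "", properties = list(
               concept_property("parent", "Z", "code"))))
  a <- validated_cs(cs, allow_dangling = TRUE)
  b <- validated_cs(cs, allow_dangling = TRUE)
  expect_identical(issues_as_data_frame(a), issues_as_data_frame(b))
  expect_identical(codes_of(a),
                   c("duplicate-code", "dangling-parent", "empty-display"))
})

test_that("simple cycles and chains are classified correctly", {
  expect_identical(
    detect_parent_cycles(data.frame(from = c("A", "B"), to = c("B", "A"))),
    list(c("A", "B")))
  expect_identical(
    detect_parent_cycles(data.frame(from = c("A", "B"), to = c("B", "C"))),
    list())
  expect_identical(
    detect_parent_cycles(data.frame(from = "A", to = "A")),
    list("A"))
  # poly-hierarchy (diamond) is legal
  expect_identical(
    detect_parent_cycles(data.frame(from = c("D", "D", "B", "C"),
                                    to = c("B", "C", "A", "A"))),
    list())
})

test_that("a rewired edge in a random DAG yields exactly the seeded cycle", {
  # brute-force DFS oracle, independent of the implementation
  dfs_cycle_nodes <- function(edges) {
    adj <- split(edges$to, edges$from)
    nodes <- unique(c(edges$from, edges$to))
    color <- stats::setNames(rep(0L, length(nodes)), nodes)
    in_cycle <- character()
    visit <- function(u, stack) {
      color[[u]] <<- 1L
      for (v in adj[[u]] %||% character()) {
        if (color[[v]] == 1L) {
          in_cycle <<- c(in_cycle, stack[seq(match(v, stack), length(stack))])
        } else if (color[[v]] == 0L) {
          visit(v, c(stack, v))
        }
      }
      color[[u]] <<- 2L
    }
    `%||%` <- function(a, b) if (is.null(a)) b else a
    for (n in nodes) if (color[[n]] == 0L) visit(n, n)
    sort(unique(in_cycle))
  }

  f <- withr::local_tempfile()
  generate_table(fixture_spec(1000, seed = 7), f)
  t <- read_delimited_table(f)
  parents <- t$cells[, 4L]
  codes <- t$cells[, 1L]
  edges <- data.frame(from = codes[nzchar(parents)],
                      to = parents[nzchar(parents)],
                      stringsAsFactors = FALSE)
  expect_identical(detect_parent_cycles(edges), list())
  expect_identical(dfs_cycle_nodes(edges), character())

  # rewire: make some node's parent point at one of its own descendants
  child <- edges$from[[50L]]
  anc <- child
  repeat {
    nxt <- edges$to[edges$from == anc][1L]
    if (is.na(nxt)) break
    anc <- nxt
  }
  edges <- rbind(edges, data.frame(from = anc, to = child))
  got <- detect_parent_cycles(edges)
  expect_length(got, 1L)
  expect_identical(sort(got[[1L]]), dfs_cycle_nodes(edges))
})

test_that("ValueSet and ConceptMap structural rules are enforced", {
  doc <- fsh_parse(c("ValueSet: DemoVS", '* ^url = "http://example.org/vs"',
                     "* ^status = #active"))
  meta <- fsh_interpret_metadata(doc$items[[1L]], "R4B")
  r <- assemble_resource(meta, content_bundle("valueset", list(
    vs_compose_entry("include", system = "http://example.org/cs"))), "R4B")
  # damage the tree the way a faulty plugin could: no system, concept+filter
  r$compose$include[[1L]] <- list(
    concept = json_array(list(list(code = "A"))),
    filter = json_array(list(list(property = "p", op = "=", value = "v"))))
  found <- validate_structure(r, "R4B")
  expect_setequal(codes_of(found), "vs-compose-invalid")
  expect_length(found, 2L)

  # constructor-level invariants reject the same shapes outright
  expect_error(vs_compose_entry("include"),
               class = "fshforge_vs_compose_invalid")
  expect_error(vs_compose_entry("include", system = "http://x",
                                concepts = list(list(code = "A")),
                                filters = list(list(property = "p",
                                                    op = "=", value = "v"))),
               class = "fshforge_vs_compose_invalid")
})
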