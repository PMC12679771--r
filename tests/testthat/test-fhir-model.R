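cs_meta <- function(extra_rules = character(), mode = "R4B") {
  doc <- fsh_parse(c("CodeSystem: DemoCS",
                     "Id: demo",
                     '* ^url = "http://example.org/cs"',
                     "* ^status = #active",
                     extra_rules))
  fsh_interpret_metadata(doc$items[[1L]], mode, doc$aliases)
}

test_that("implicit properties are auto-declared and count is computed", {
  bundle <- content_bundle("codesystem", list(
    concept_entry("A", display = "Root"),
    concept_entry("B", display = "Leaf",
                  properties = list(concept_property("parent", "A", "code")))))
  r <- assemble_resource(cs_meta(), bundle, "R4B")
  expect_identical(r$count, 2L)
  expect_length(r$property, 1L)
  expect_identical(r$property[[1L]]$code, "parent")
  expect_identical(r$property[[1L]]$uri,
                   "http://hl7.org/fhir/concept-properties#parent")
  expect_identical(r$property[[1L]]$type, "code")
  expect_identical(r$concept[[2L]]$property[[1L]]$valueCode, "A")
})

test_that("count totals concepts at all nesting levels", {
  nested <- content_bundle("codesystem", list(
    concept_entry("A"),
    concept_entry("B", children = list(
      concept_entry("B1"),
      concept_entry("B2"))),
    concept_entry("C")))
  r <- assemble_resource(cs_meta(), nested, "R4B")
  # independent brute-force node count
  count_all <- function(arr) {
    if (is.null(arr)) {
      return(0L)
    }
    total <- 0L
    for (c in arr) total <- total + 1L + count_all(c$concept)
    total
  }
  expect_identical(r$count, 5L)
  expect_identical(count_all(r$concept), 5L)
})

test_that("undeclared concept properties are refused at assembly", {
  bundle <- content_bundle("codesystem", list(
    concept_entry("A", properties = list(
      concept_property("validity", "x", "code")))))
  expect_error(assemble_resource(cs_meta(), bundle, "R4B"),
               class = "fshforge_undeclared_property")
  declared <- cs_meta(c("* ^property[0].code = #validity",
                        "* ^property[0].type = #code"))
  r <- assemble_resource(declared, bundle, "R4B")
  expect_identical(r$property[[1L]]$code, "validity")
})

test_that("an empty CodeSystem serializes with count 0 and no concept", {
  r <- assemble_resource(cs_meta(), content_bundle("codesystem", list()),
                         "R4B")
  txt <- serialize_fhir(r, "R4B")
  expect_match(txt, '"count": 0', fixed = TRUE)
  expect_false(grepl('"concept"', txt))
  expect_match(txt, '^\\{\n  "resourceType": "CodeSystem"')
})

test_that("serialization is byte-deterministic and round-trips", {
  bundle <- content_bundle("codesystem", list(
    concept_entry("A", display = "Root"),
    concept_entry("B", properties = list(
      concept_property("parent", "A", "code"),
      concept_property("inactive", TRUE, "boolean")))))
  r <- assemble_resource(cs_meta(), bundle, "R4B")
  t1 <- serialize_fhir(r, "R4B")
  t2 <- serialize_fhir(r, "R4B")
  expect_identical(t1, t2)
  parsed <- jsonlite::fromJSON(t1, simplifyVector = FALSE)
  expect_identical(parsed$resourceType, "CodeSystem")
  expect_identical(parsed$count, 2L)
  expect_identical(parsed$concept[[2L]]$property[[2L]]$valueBoolean, TRUE)
  expect_identical(names(parsed)[1L], "resourceType")
})

test_that("ValueSet compose entries build include/exclude", {
  doc <- fsh_parse(c("ValueSet: DemoVS", "Id: demo-vs",
                     '* ^url = "http://example.org/vs"',
                     "* ^status = #active"))
  meta <- fsh_interpret_metadata(doc$items[[1L]], "R4B")
  bundle <- content_bundle("valueset", list(
    vs_compose_entry("include", system = "http://example.org/cs",
                     concepts = list(list(code = "A", display = "Root"))),
    vs_compose_entry("exclude", system = "http://example.org/cs",
                     filters = list(list(property = "inactive", op = "=",
                                         value = "true")))))
  r <- assemble_resource(meta, bundle, "R4B")
  expect_identical(r$compose$include[[1L]]$concept[[1L]]$code, "A")
  expect_identical(r$compose$exclude[[1L]]$filter[[1L]]$op, "=")
  expect_match(serialize_fhir(r, "R4B"), '"compose"')
})

cm_fixture <- function(correspondence) {
  doc <- fsh_parse(c("Instance: DemoCM", "InstanceOf: ConceptMap",
                     "Usage: #definition",
                     '* url = "http://example.org/cm"',
                     "* status = #active"))
  meta <- fsh_interpret_metadata(doc$items[[1L]], "R4B")
  bundle <- content_bundle("conceptmap", list(
    cm_group("http://example.org/src", "http://example.org/tgt",
             elements = list(list(code = "a", targets = list(
               list(code = "x", correspondence = correspondence)))))))
  list(meta = meta, bundle = bundle)
}

test_that("ConceptMap correspondence uses the mode's element and vocabulary", {
  fx <- cm_fixture("equivalent")
  r4 <- assemble_resource(fx$meta, fx$bundle, "R4B")
  expect_identical(r4$group[[1L]]$element[[1L]]$target[[1L]]$equivalence,
                   "equivalent")
  r5 <- assemble_resource(fx$meta, fx$bundle, "R5")
  expect_identical(r5$group[[1L]]$element[[1L]]$target[[1L]]$relationship,
                   "equivalent")
  expect_false(grepl("equivalence", serialize_fhir(r5, "R5")))

  fx <- cm_fixture("relatedto")
  expect_s3_class(assemble_resource(fx$meta, fx$bundle, "R4B"),
                  "fhir_resource")
  expect_error(assemble_resource(fx$meta, fx$bundle, "R5"),
               class = "fshforge_mode_vocabulary")
  fx <- cm_fixture("source-is-narrower-than-target")
  expect_error(assemble_resource(fx$meta, fx$bundle, "R4B"),
               class = "fshforge_mode_vocabulary")
})

test_that("R5-only metadata serializes in R5 and the gate catches leaks", {
  meta5 <- cs_meta('* ^editor.name = "Jo"', mode = "R5")
  r5 <- assemble_resource(meta5, content_bundle("codesystem", list()), "R5")
  txt <- serialize_fhir(r5, "R5")
  expect_match(txt, '"editor"')
  # a tree assembled for one mode cannot be serialized as the other
  expect_error(serialize_fhir(r5, "R4B"), class = "fshforge_invalid_mode")
})

test_that("modes are explicit and validated", {
  expect_identical(as.character(fhir_mode("r4b")), "R4B")
  expect_identical(as.character(fhir_mode("R5")), "R5")
  expect_error(fhir_mode("R4"), class = "fshforge_invalid_mode")
})
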