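Package: fshforge
Title: Compile FSH Terminology Sources into FHIR CodeSystem, ValueSet and
    ConceptMap JSON
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compiler toolkit for providing terminologies as HL7 FHIR
    resources. Resource metadata (canonical URL, version, status, publisher,
    property declarations, ...) is authored in a strict terminology-focused
    subset of the FHIR Shorthand (FSH) language, while resource content
    (concepts, value-set composition, mapping groups) is produced by plugins
    configured through structured block comments embedded in the source
    files.  The flagship plugin converts delimited text catalogs
    (comma/tab/pipe separated) into CodeSystem concepts with configurable
    code, display, property and hierarchy column mappings.  Assembled
    resources are structurally validated (duplicate codes, dangling parents,
    hierarchy cycles, property declarations) and serialized as canonical,
    byte-deterministic FHIR JSON in either the R4B or the R5 dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
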