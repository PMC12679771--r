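// Complete source file for converting a synthetic diagnosis index catalog
// (headerless pipe-separated table, one concept per row) into a FHIR
// CodeSystem.  The table is generated by the package's fixture generator
// (layout "alpha_like"); it emulates the shape of national index catalogs
// but contains no real data.

Alias: $props = http://example.org/fhir/concept-properties

// Core metadata shared by every yearly version of the catalog.
RuleSet: catalog-metadata
* ^url = "http://example.org/fhir/CodeSystem/synthetic-alpha"
* ^publisher = "Example Terminology Unit"
* ^copyright = "Synthetic data; free to use."
* ^status = #active
* ^experimental = false
* ^caseSensitive = true
* ^content = #complete
* ^property[0].code = #primary-code
* ^property[0].uri = $props
* ^property[0].type = #code
* ^property[1].code = #secondary-code
* ^property[1].type = #code
* ^property[2].code = #orpha
* ^property[2].type = #code

// Release-specific bits are parameterized so that publishing another
// yearly version needs only a handful of lines.
RuleSet: catalog-version(ver, reldate)
* insert catalog-metadata
* ^version = "{ver}"
* ^date = "{reldate}"

CodeSystem: SyntheticAlphaCatalog
Id: synthetic-alpha-2025
Title: "Synthetic Alpha Index Catalog, 2025 release"
Description: "Index terms mapped to stable codes, with primary and secondary classification codes and rare-disease identifiers where available. Entries flagged invalid in the source are carried as inactive concepts."
* insert catalog-version(2025, 2025-01-01)

/*^babelfsh delimited-table
    --file synthetic-alpha-2025.psv
    --delimiter "|"
    --no-header
    --code-column 2
    --display-column 7
    --property primary-code=3:code
    --property secondary-code=4:code
    --property orpha=6:code
    --inactive-column 1
    --inactive-true-values 0
^babelfsh*/
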