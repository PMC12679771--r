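# fshforge

Compile FSH terminology sources into HL7 FHIR CodeSystem, ValueSet and
ConceptMap JSON.

## The problem

FHIR terminology servers can only serve what exists as FHIR resources, but
most code systems are distributed in other shapes: pipe-separated index
catalogs, CODE/DISPLAY spreadsheets exported from curation tools, and so
on. Writing the conversion by hand does not scale — a catalog of ~90,000
concepts expressed as native FSH concept rules balloons into hundreds of
thousands of source lines and brings general-purpose FSH compilers to their
knees, because they were built for profiles, not for bulk content.

`fshforge` splits the job in two:

* **Metadata** (canonical URL, version, status, publisher, identifiers,
  concept property declarations, …) is authored in a strict,
  terminology-focused subset of the FHIR Shorthand (FSH) language —
  item declarations, caret value rules, parameterized RuleSets, aliases.
  Every fshforge source file is also a valid FSH file.
* **Content** (the concepts themselves, value-set composition, mapping
  groups) is produced by *plugins* configured through a structured block
  comment embedded in the source, recognized by the token pair
  `/*^babelfsh … ^babelfsh*/`. Ordinary `/* … */` comments are untouched.
  The flagship `delimited-table` plugin converts CSV/TSV/pipe tables with
  configurable code/display/property/hierarchy column mappings.

Assembled resources are structurally validated (duplicate codes, dangling
parents, hierarchy cycles, undeclared properties, …) and serialized as
canonical, byte-deterministic FHIR JSON in either the **R4B** or the **R5**
dialect — one mode per invocation, selected explicitly. Plugins never see
FHIR element names; version-agnostic proxy objects are rendered into the
mode's element tree only at write-out (R4B `equivalence` vs. R5
`relationship` in ConceptMap being the sharpest divergence; the two
vocabularies are never translated automatically).

## A worked example

A curation tool exported `lab.csv`:

```
CODE,DISPLAY,INACTIVE,PARENT
C0001,Abscess acute,NO,
C0002,Disease polyp,NO,C0001
C0003,Dysplasia lesion polyp,NO,
C0004,Abscess infection,NO,C0003
C0005,Benign embolism sclerosis,YES,C0002
C0006,Abscess occlusion primary,NO,
```

The complete source file `lab.babel.fsh` next to it:

```
CodeSystem: LabDemo
Id: lab-demo
Title: "Demonstration laboratory code system"
* ^url = "http://example.org/fhir/CodeSystem/lab-demo"
* ^version = "1.0"
* ^status = #active
* ^caseSensitive = true
* ^content = #complete
/*^babelfsh delimited-table --file lab.csv --display-column DISPLAY
    --inactive-column INACTIVE --parent-column PARENT ^babelfsh*/
```

Compile it, from R:

```r
library(fshforge)
res <- fsh_compile(".", fhir_version = "r4b", out_dir = "out")
print(res)
#> <fsh_compile_result> ok: 1 resource(s) written, 0 issue(s)
```

or from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","fshforge",package="fshforge"))')" \
    compile --fhir-version r4b --out out .
```

The written `out/CodeSystem-lab-demo.json` begins:

```json
{
  "resourceType": "CodeSystem",
  "id": "lab-demo",
  "url": "http://example.org/fhir/CodeSystem/lab-demo",
  "version": "1.0",
  "name": "LabDemo",
  "title": "Demonstration laboratory code system",
  "status": "active",
  "caseSensitive": true,
  "content": "complete",
  "count": 6,
  "property": [
    {
      "code": "parent",
      "uri": "http://hl7.org/fhir/concept-properties#parent",
      "type": "code"
    },
    {
      "code": "inactive",
      "uri": "http://hl7.org/fhir/concept-properties#inactive",
      "type": "boolean"
    }
  ],
  ...
}
```

`count` is the total number of concepts (6: one per table row), the
`PARENT` column became `parent` properties (e.g. concept `C0002` carries
`parent = C0001`), the `YES` in the `INACTIVE` column became
`inactive = true` on `C0005`, and both implicit properties were
auto-declared with their standard URIs. The exit code is 0 on success, 1 on
any compile or validation error, 2 on usage errors — CI-friendly.

A larger, complete definition of a synthetic ~90,000-row index catalog —
full metadata, RuleSet re-use for versioning, and a headerless pipe-file
directive — ships in
`inst/extdata/synthetic-alpha-catalog.babel.fsh` (50 lines in total).

## Plugins

A plugin declares its arguments (long/short flags, types, defaults,
mutually exclusive groups, help texts) and implements one content
generator; the framework derives the argument parser, the validation
messages and the generated help (`fshforge help delimited-table`, or a
directive whose only argument is `--help`) from the same declaration.
Built-ins: `delimited-table` (CodeSystem), `code-list` (ValueSet),
`mapping-table` (ConceptMap). Third-party packages add plugins by calling
`register_plugin()` from their `.onLoad()`; ids must be unique.

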