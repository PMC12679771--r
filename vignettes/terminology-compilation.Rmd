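---
title: "Compiling terminology sources into FHIR: the fshforge pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling terminology sources into FHIR: the fshforge pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fshforge)
```

## The compilation model

`fshforge` treats a terminology release as two independent inputs that are
only joined at the very end:

1. **Declarative metadata**, written in a strict subset of FHIR Shorthand
   (FSH). The subset covers exactly what terminology resources need: item
   declarations (`CodeSystem:`, `ValueSet:`, `Instance:` of `ConceptMap`),
   the `Id:`/`Title:`/`Description:` keywords, caret value rules on an
   allowlisted metadata surface, aliases, and parameterized RuleSets.
   Everything else in FSH — profiles, extensions, path rules, and in
   particular *concept rules* — is rejected with a targeted message.
   Rejecting inline concepts loudly is deliberate: content authored as FSH
   rules is precisely the failure mode this design avoids, and silently
   ignoring such rules would mask author errors.
2. **Generated content**, produced by a plugin named in a directive comment
   (`/*^babelfsh <plugin-id> <argv> ^babelfsh*/`). Because the directive is
   a syntactically ordinary block comment, every source file remains valid
   FSH; deleting all directives changes nothing about the parse of the
   remaining code (a property the test suite asserts file by file).

Two parsing details are worth noting. Encoding is UTF-8 only, with a BOM
tolerated and stripped. And a `//` line comment opens only at the start of
a line or after whitespace, so unquoted URLs in alias values
(`Alias: $cs = http://…`) survive comment stripping intact.

The per-item pipeline is: parse → expand RuleSets → interpret metadata →
resolve plugin → parse plugin arguments → generate content → assemble →
validate → serialize. Items compile independently; one item's failure
leaves its siblings untouched (unless `fail_fast`).

### Directive binding rules

A directive binds to the item whose lexical extent (declaration line up to
the line before the next item or RuleSet declaration) contains it, and each
compiled item must carry **exactly one** directive. Both rules are choices:
lexical binding is the least surprising reading of "the comment under the
item", and the one-directive cardinality keeps the split honest —
metadata-only items belong in plain FSH and a general chaining mechanism
for multiple content plugins per item would have no defined merge
semantics. A directive outside any item extent is a compile error rather
than being attached to the nearest item, again to avoid guessing.
Whether whitespace may separate `/*` from the recognition token was also
open; we require strict adjacency, matched case-sensitively, so that the
recognition can never fire inside prose.

### RuleSet expansion

`insert` rules are expanded by **textual** substitution of `{parameter}`
placeholders, after which the substituted lines are re-parsed as rules.
This soft-parse order matters: it allows an argument to contribute any
token, e.g. a version literal or part of a URL. Literal `,` and `)` inside
arguments are escaped with `\`. Expansion is recursive (RuleSets may insert
RuleSets) with an explicit stack, so direct or transitive self-insertion is
reported as a cycle instead of hanging. RuleSets share one project-wide
namespace across all source files of a compilation — the reuse patterns
that motivate RuleSets (yearly versions of one catalog factored over a
shared metadata block) routinely span files — and a name defined twice in
the project is an error rather than a silent shadow.

## The delimited-table plugin

The flagship plugin converts one delimited text table into CodeSystem
concepts. The tunable surface, with defaults:

| argument | default | meaning |
|---|---|---|
| `--delimiter` | `,` | one character; `TAB` accepted for a tab stop |
| `--encoding` | `utf-8` | or `latin1`; anything undecodable is an error with a byte offset |
| `--no-header` | off | with it, columns are addressed by 1-based index |
| `--code-column` | `CODE` | the only mandatory mapping; blank code cells are errors |
| `--hierarchy` | `parent` | `parent` / `child` / `both` properties, or `nested` concept elements |
| `--inactive-true-values` | `YES,Y,TRUE,1` | case-insensitive cell values flagging deprecation |
| `--allow-dangling-parents` | off | downgrade unresolved parent references to warnings |

`parent` is the default hierarchy representation because the
property-based form is what terminology servers generally prefer over
nested concept elements, and linking child-to-parent is the direction
catalogs typically ship. `nested` mode refuses concurrent parent/child
property mappings, since the FHIR standard says the two representations
must not be mixed. Dangling parents default to errors because a forward
reference usually means a truncated extract, but they are downgradable —
real catalogs do ship partial extracts on purpose. Rows sharing a code are
merged into one concept accumulating properties in row order (the behavior
established by tabular import tools in this space); merged rows that
disagree on display or definition are an error, not a last-one-wins.

Cells are taken verbatim — no trimming — because index catalogs carry
significant whitespace more often than one would hope. RFC-4180
double-quote escaping applies to comma and semicolon tables only; pipe and
tab tables are raw splits, matching how such catalogs are actually
distributed (unquoted). Quoted cells may not span physical lines; this is a
documented dialect restriction.

## Version-agnostic assembly and canonical serialization

Plugins emit proxy objects (`concept_entry`, `vs_compose_entry`,
`cm_group`) that contain no FHIR element names. Only `assemble_resource()`
and `serialize_fhir()` consult the mode:

* R5-only metadata paths (`editor`, `reviewer`, `copyrightLabel`,
  `approvalDate`, …) are refused in R4B mode at interpretation time,
  because the R4B validator would reject them downstream anyway — failing
  early with the offending line beats a late validator message.
* ConceptMap correspondence codes must belong to the active mode's
  vocabulary (R4B `equivalence` vs. R5 `relationship`). `equivalent` exists
  in both; everything else differs, and no automatic translation is
  attempted — the two vocabularies do not map one-to-one, and a wrong
  guess in a mapping resource is worse than an error.

Serialization is canonical and byte-deterministic: UTF-8, `resourceType`
first, element order following the FHIR definition order for the mode,
2-space indentation, LF endings, one trailing newline. `count` is always
computed and emitted for CodeSystem (total concepts at all nesting levels)
— the element is optional in FHIR but terminology servers rely on it, and
it doubles as the completeness check: for a table with unique codes,
`count` must equal the data-row count. Implicit properties (`parent`,
`child`, `inactive`, `deprecated`, `notSelectable` — the full standard set,
not just the commonly seen three) are auto-declared on first use with
`http://hl7.org/fhir/concept-properties#<code>` URIs; declared properties
keep their declaration order, implicit ones follow in order of first use
in the concept stream. Output files are named
`<ResourceType>-<id>.json`; a collision between two items is an error.
Decimal literals are carried as verbatim text end to end, so `1.10` is
emitted as written.

## Validation

Structural validation returns severity-tiered issues instead of raising:
errors block writing, warnings never do. Checks include required elements
(`status`; CS `content`), URL syntax, duplicate concept codes, property
use/declaration consistency, unresolved parent/child values, hierarchy
cycles, concurrent nested+property hierarchies (warning), the computable
name convention (warning), empty displays (warning), compose-entry
invariants and the mode's correspondence vocabulary. Multiple parents are
legal and produce no finding — rare-disease nomenclatures in particular
define forests and poly-hierarchies on purpose. Cycle detection runs on
the code→parent graph via strongly connected components; each cyclic
component is reported once, as the cycle walked from its lexicographically
smallest member with smallest-successor tie-breaks, so output is
deterministic. Issue order is stable: document order, then check order.

Deep validation against the full FHIR validation engine is out of scope by
design; `fsh_compile(deep_validate = <command>)` exposes a hook that runs
an external command per written file and relays non-zero exits as
warnings, never as errors.

## What the synthetic fixtures emulate — and what they do not

The generator produces two layouts: `hierarchy_csv`
(CODE/DISPLAY/INACTIVE/PARENT with header; random forest hierarchy capped
at depth 3, ~70% of non-root rows linked to a parent, 15% of rows flagged
inactive, optional duplicate-code rows that add a second parent) and
`alpha_like`, a headerless 7-column pipe format
(`validity|code|primary-code|secondary-code|extra-code|orpha|text`)
emulating the *shape* of national diagnosis index catalogs: a validity
flag, a stable identifier, mapped classification codes, a rare-disease
identifier where applicable, and free-text index terms. It deliberately
does **not** replicate any official column layout, licensed content, or
real-world quirks such as mixed encodings within one file, BOM-prefixed
headers, or vendor-specific quoting. Passing tests therefore demonstrate
the compiler's semantics and scale behavior, not robustness against every
catalog in the wild; the column mapping surface is the tool for the
latter. The inactive fraction and hierarchy density are fixed, documented
choices of what a mid-sized clinical catalog plausibly looks like, set
once before any testing. Display text is drawn from a fixed clinical word
list with a seeded RNG; identical spec and seed give byte-identical files,
and each planted defect (display conflict, dangling parent, cycle, ragged
row) is recorded in the manifest with its line so tests can assert exact
findings.

The independent oracle (`oracle_codesystem()`) rebuilds the expected JSON
by naive row-by-row iteration, sharing nothing with the compiler except
the canonical JSON writer, and is restricted to small tables (≤ 1,000
rows) on purpose. The test suite asserts byte equality between compiler
and oracle over 200 seeded fixtures.

## Problem sizes and performance

The scale checks compile a 90,400-row pipe catalog — the size of a
full-year national index release — in roughly 10 s on one CPU, dominated
by concept-tree construction; serialization itself is a compiled-code tree
walk. The linearity check compares 10,000 against 100,000 rows. The
33-row worked example compiles in well under a second. These sizes are the
package's own benchmark conditions and are re-derived from scratch by
`scripts/acceptance.R` on every run.

## Known limitations

* Only delimited text content plugins ship; XML-based classification
  formats, OWL ontologies, spreadsheets and web-API sources need
  third-party plugins (the contract is two functions and a descriptor).
* The FSH subset excludes profiles, extensions-as-items and concept rules
  by design; `Instance:` items are accepted for ConceptMap only. Whether
  other instance types deserve support was left open; restricting to the
  one type with defined content semantics was the conservative choice.
* ValueSet content generation is minimal (enumerated code lists);
  intensional definitions are better served by general-purpose FSH
  tooling.
* Plugin argument vectors do not resolve FSH aliases; a directive is
  self-contained.
* Multi-line quoted cells in delimited input are not supported.
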