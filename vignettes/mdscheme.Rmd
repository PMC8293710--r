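---
title: "Domain-specific metadata schemes with mdscheme: model, validation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-specific metadata schemes with mdscheme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscheme)
```

## Why domain-specific schemes

Broad metadata standards such as the Ecological Metadata Language cover
entire fields, which makes them powerful but heavy: for any one research
domain most properties do not apply, and the sheer size of the standard
discourages researchers from providing metadata at all. The alternative
this package implements is a *domain-specific* metadata scheme — a small,
purpose-built scheme, as complex as necessary and as simple as possible,
typically co-developed between a metadata-minded person and the
researchers producing the data. The researcher-facing artefact is nothing
more exotic than a spreadsheet; the machinery around it (definition,
validation, export, distribution) is this package.

The running example throughout the package is a scheme for experimental
microbial ecology: protist microcosm experiments with several species,
treatments, measurement devices, and data-processing steps, producing a
handful of delimited data files per experiment.

## The scheme model

A **scheme** (`md_scheme()`) is a named, versioned, ordered list of
**property sets** (`md_property_set()`), each an ordered list of
**properties** (`md_property()`). A property has:

* a `type` from `character`, `integer`, `real`, `logical`, `date`
  (ISO-8601 `YYYY-MM-DD`). This is deliberately the smallest set that
  covers spreadsheet-entered experimental metadata; richer types (units,
  URIs, taxon identifiers) can be expressed as `character` plus a
  vocabulary.
* a `required` flag;
* at most one vocabulary: `allowed` (closed — anything else is an
  **error**) or `suggested` (open — anything else is only a **note**);
* an optional inclusive numeric range `min_value`/`max_value` (numeric
  types only);
* an optional cross-reference `refers_to = c(set, property)`: every
  non-empty value must occur in the referenced column. Cross-references
  are declared, not inferred, so that consistency checking and per-file
  export have an explicit, auditable basis.

Property sets carry a `cardinality`: `exactly-one-row` for
experiment-level sheets that hold a single record, `zero-or-more-rows`
for per-record sheets (species, treatments, files, ...). This distinction
mirrors how experimental metadata naturally splits into "about the whole
experiment" and "about each thing in it".

`check_scheme_definition()` verifies the model invariants (unique
whitespace-free names, vocabulary/type coherence, range ordering,
resolvable references) and *returns* problems rather than raising, so a
scheme under construction can be inspected. All editing operations
(`add_property_set()`, `add_property()`, `remove_property_set()`) have
value semantics — they return a new scheme — which keeps iterative
co-development reproducible.

Schemes serialize to a JSON manifest (`write_scheme_json()`), the
machine-readable form shipped inside scheme packages.

## The entry workbook

`write_template_workbook()` renders a scheme as an XLSX workbook: one
worksheet per property set plus a leading `_scheme` identity sheet (scheme
name, version, per-sheet cardinality). Each property sheet has four header
rows — names, descriptions, `type[:required]` markers, and the vocabulary
as `allowed:a|b` / `suggested:a|b` — with data starting in row 5. The
layout is self-describing; there are no hidden cells, formulas or
styling-dependent semantics.

Reading (`read_metadata_workbook()`) is deliberately *schema-light*: every
cell comes back verbatim as a string, whitespace-trimmed, with trailing
all-empty rows dropped; the empty string is the missing value (no `NA`
sentinel, since spreadsheet users leave cells blank). One value per cell;
multiplicity is extra rows, never in-cell delimiters. Unknown sheets and
columns are retained rather than dropped, because the validator — not the
reader — is responsible for reporting them. Typing happens only at
validation and export time.

A diff-friendly plain-text twin exists (`write_metadata_csvdir()`): one
RFC-4180 CSV per sheet plus a JSON identity file. Both representations
round-trip to identical metadata objects, and both are byte-deterministic
(workbook archives are written with fixed member timestamps), so fixtures
and packages can be compared byte for byte.

## The validation model

Validation runs in four stages and never raises on findings; every
finding is an issue with a **stable rule code** (see `rule_registry()`)
and a fixed severity under the total order *error > warning > note*:

1. **structure** — tables against the scheme: scheme id mismatch, missing
   set/column (error), unknown set/column (warning), wrong row count for
   exactly-one-row sets (error);
2. **values** — per declared cell: required-but-missing, type parse
   failure, closed-vocabulary violation, range violation (all errors), and
   open-vocabulary deviation (note). At most one issue per cell, checked
   in the order required → type → allowed → range → suggested, so an
   unparseable value is reported once as a type problem rather than
   cascading;
3. **consistency** — cross-references must resolve (error), repeated
   values of a set's first (key) property are flagged once per duplicated
   value (warning), and a data file assigned more than one row of the
   designated data-file set — i.e. more than one measurement and
   extraction method — is an error. That one-method-per-file constraint is
   what later makes the per-file export (and any mapping onto a broader
   standard) unambiguous;
4. **data** — the designated data-file and data-column sets against the
   files on disk: missing declared file / column and type-violating column
   content are errors; undeclared files and header columns are warnings.
   Column type checking reads all rows by default (`max_rows` caps it;
   the files this targets are desk-scale).

Two cross-cutting choices:

* **Cascade suppression.** A table with an error-level *structural*
  problem is excluded from the value, consistency and data stages, and
  consistency rules whose referenced table is excluded are skipped. A
  single missing column therefore produces one structural error, not a
  storm of follow-on issues. A scheme-id mismatch does not suppress
  anything — the tables can still be checked.
* **Exact, case-sensitive vocabulary matching.** Vocabularies are
  deterministic controlled lists; fuzzy matching would hide exactly the
  inconsistencies the validator exists to surface.

Warning-level severities (unknown sheet/column, duplicate key, undeclared
file/column) are this package's choices: they flag things that are
suspicious but never block export; errors are reserved for violations of
explicit declarations.

`validate_all()` assembles a report whose `worst` field is the maximum
severity present (or `"success"`); `render_report()` renders it as
markdown or HTML with a summary line (`E errors / W warnings / N notes`)
and one entry per issue under its stage and property set. Rendering is
deterministic given the report; only the timestamp varies between runs.

## XML export

`export_xml()` serializes metadata in scheme order: root element named
after the scheme (with a `schemeVersion` attribute and namespace
`urn:mdscheme:<name>:<version>`), one child element per property set, one
`<record>` per row, one leaf element per non-empty value — missing values
are absent elements. Export is **gated**: it refuses whenever validation
finds at least one error-level issue, and proceeds with warnings or notes
only. The gate can be switched off (`validate = FALSE`) solely to preview
the serialization of still-empty template metadata.

`export_xml_per_datafile()` writes one self-contained document per
declared data file. Experiment-level (exactly-one-row) sets are replicated
verbatim into every document; multi-row records are assigned to files by
propagating file associations along declared cross-references, in both
directions, to a fixed point — with the one restriction that data-file
rows never *relay* associations between other rows (otherwise two files
sharing a measurement would leak into each other's documents). Records
associated with exactly one file appear in exactly that file's document;
records associated with no file (species, treatments) are conservatively
replicated everywhere, so each document stands alone.

`read_metadata_xml()` inverts the combined export. Passing the scheme
aligns column order exactly (including columns that happen to be entirely
empty); without it, columns are reconstructed in order of first
appearance.

`eml_mapping_stub()` is the hook towards broader standards: it reports
which scheme properties are covered by a property-path → EML-path mapping
and which mapping entries dangle. Actual EML emission is out of scope.

## The scheme repository

`pack_scheme()` bundles manifest, template workbook and validated example
workbooks into `<name>_<version>.zip`; packaging refuses examples with
validation errors. Two checksums serve two purposes: the package manifest
carries a SHA-256 over the member contents (so unpack → repack is a fixed
point), and the repository index carries the SHA-256 of each archive file
(so `install_scheme()` can detect tampering or corruption). A repository
is just a directory — local or behind a static URL — with an `index.json`;
there is no server-side logic. `"latest"` resolves by strict numeric
semantic-version ordering with pre-releases excluded, and installation
unpacks into a per-session temporary directory by default, never touching
the repository or the user's library. Unlike designs that ship executable
companion code with each scheme, packages here are pure data; all
validation behaviour is driven by the declarative scheme definition.

## The synthetic-data generator and what the tests show

`make_example_scheme()` builds the seven-set example scheme
(`Experiment`, `Species`, `Treatment`, `Measurement`, `DataExtraction`,
`DataFiles`, `DataFileColumns`); `make_filled_metadata()` fills it so that
a clean generation validates with *zero* issues, and
`make_toy_datafiles()` writes matching delimited files (declared header,
five typed data rows each — small enough for instant tests, enough rows to
exercise type checking).

The generator is also the test oracle. A *fault specification* maps rule
codes to counts; the generator seeds exactly that many independent
violations at randomly chosen (seeded) sites and records the precise
`(code, severity, location)` triples the validator must report. Site
pools for different rules are disjoint by construction, rows carrying a
seeded bad cell are never duplicated by row-level faults, and structural
faults only touch tables no other fault uses — so expectations compose
additively across rules. Over-seeding beyond the available sites is an
error, not a silent cap; in particular the example scheme has one
exactly-one-row set and one scheme id, so at most one row-count and one
id-mismatch fault can be seeded. Default generation sizes used throughout
the tests are 3–6 species and 3–6 data files; the property-based suite
re-checks the oracle across 100 randomized seed/code/count combinations.

What passing tests do **not** show about real data: the generator produces
tidy, regular tables with invented vocabularies; real workbooks contain
typographic creativity (smart quotes, thousands separators, locale date
formats) that will surface as type errors rather than being repaired, and
real data files may be large, oddly delimited or encoded in ways the
RFC-4180 reader rejects. The validator reports such files as unreadable
rather than guessing.

## Numerical and degenerate-input choices

* Types parse by strict grammar: integers `[+-]?digits`, reals with
  optional fraction/exponent, logicals `TRUE`/`FALSE` (case-insensitive),
  dates `YYYY-MM-DD` that survive a calendar check. No locale-dependent
  parsing.
* Range checks are inclusive on both ends and run only on values that
  already parsed.
* Duplicate-key and multiple-method findings are located at the *second*
  occurrence, once per duplicated value, so k duplicates yield k issues,
  not k² pairs.
* Empty tables are legal everywhere: a scheme with zero declared data
  files exports an empty per-file mapping without error.
* Archives embed a fixed member timestamp, making every generated
  artefact byte-reproducible under a fixed seed.

## Limitations

* No GUI or web front end; the interfaces are R functions, the `mdscheme`
  command-line script and the workbook itself.
* No scheme inheritance or composition, and no executable per-scheme
  extensions; consistency rules are limited to what `refers_to` and the
  data-file designations can express.
* Reports render to markdown and HTML only.
* EML support is a mapping-coverage stub, not an emitter.
* Remote repositories are static file trees; there is no publishing
  protocol.
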