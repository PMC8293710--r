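# mdscheme

Small, domain-specific metadata schemes for research data: define a
scheme, hand researchers a spreadsheet generated from it, validate what
comes back at three levels with error/warning/note severities, export
error-free metadata to XML (combined, or one document per data file), and
distribute schemes through a simple versioned repository.

Broad standards such as the Ecological Metadata Language cover whole
fields and are correspondingly heavy. `mdscheme` targets the opposite end:
a bespoke scheme for one research domain — as complex as necessary, as
simple as possible — whose entry interface is nothing more than a
multi-sheet workbook. The bundled example scheme describes experimental
microbial ecology data (protist microcosms: species, treatments,
measurement devices, extraction software, data files and their columns).

## The model in brief

A scheme `S` is an ordered list of property sets; each property has a type
`t ∈ {character, integer, real, logical, date}`, a `required` flag, at
most one vocabulary (closed `allowed` or open `suggested`), an optional
range `[min, max]`, and an optional cross-reference *set.property*.
Filled metadata is a collection of raw string tables, one per property
set; the empty string means missing. Validation is a pure function
`(metadata, scheme, data files) → issues`, each issue carrying a stable
rule code (`rule_registry()`) and a severity under the total order
*error > warning > note*:

| stage       | checks                                                          |
|-------------|-----------------------------------------------------------------|
| structure   | tables vs. property sets, columns vs. properties, row counts    |
| values      | required, type, allowed (error) / suggested (note), range       |
| consistency | cross-references, duplicate keys, one measurement per data file |
| data        | declared files/columns/types vs. the actual delimited files     |

XML export refuses while any error-level issue remains; notes and
warnings never block it.

## Worked example

```r
library(mdscheme)

scheme <- make_example_scheme()              # emeScheme 0.9.9, 7 property sets
fx <- make_filled_metadata(scheme, n_species = 3, n_datafiles = 2,
                           faults = c(VAL_NOT_ALLOWED = 1, VAL_NOT_SUGGESTED = 1),
                           seed = 42)
data_dir <- tempfile()
make_toy_datafiles(fx$meta, data_dir, seed = 42)

report <- validate_all(fx$meta, scheme, data_dir = data_dir)
report
#> <md_validation_report> emeScheme_0.9.9: ERROR (1 errors / 0 warnings / 1 notes)

cat(render_report(report, "markdown"))
#> # Validation report: emeScheme_0.9.9
#>
#> - Validated: 2026-09-25T05:06:24Z
#> - Result: **ERROR**
#> - Summary: 1 errors / 0 warnings / 1 notes
#>
#> ## Stage: values
#>
#> ### Species
#>
#> - [ERROR] VAL_NOT_ALLOWED (Species/TrophicGroup, row 2): value 'parasitoid' is not in the allowed values (bacterivore, predator, omnivore, autotroph)
#> - [NOTE] VAL_NOT_SUGGESTED (Species/CultureMedium, row 2): value 'tap water' is not among the suggested values (protist pellet medium, wheat seed medium, spring water)
```

The two seeded deviations surface with exactly the documented severities:
the value outside the closed `allowed` vocabulary is an **error** (and
blocks export), the value outside the open `suggested` vocabulary is only
a **note**. A clean generation (`faults = NULL`) validates with zero
issues, after which

```r
export_xml(meta, scheme, "experiment.xml")            # one combined document
export_xml_per_datafile(meta, scheme, "xml/")         # one document per data file
pack_scheme(scheme, examples = list(filled = meta), out_dir = "repo/")
install_scheme("repo/", "emeScheme", "latest")
```

export and distribute it. The same workflow is available from a shell via
the thin wrapper in `inst/cli/`:

```sh
mdscheme validate metadata.xlsx --scheme scheme.json --data-dir data/ --report-out report.md
mdscheme export metadata.xlsx --scheme scheme.json --per-datafile --out-dir xml/
```

(exit status 0: no errors; 1: validation errors; 2: usage; 3: I/O or
repository problems).

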