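Package: mdscheme
Title: Domain-Specific Metadata Schemes: Entry Workbooks, Validation, and
    XML Export
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building small, domain-specific metadata schemes
    and putting them to work. A scheme is a named, versioned collection of
    property sets (types, required flags, allowed and suggested
    vocabularies, numeric ranges, cross-references). From a scheme the
    package generates a multi-sheet spreadsheet workbook for metadata
    entry, reads filled workbooks back, validates the metadata at three
    levels (structure against the scheme; values against types,
    vocabularies and ranges; internal consistency and conformance of the
    described tabular data files) with error, warning and note
    severities, and exports error-free metadata to XML, either combined
    or as one document per data file. Schemes are distributed as checksummed
    zip packages through a simple versioned repository index.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    readxl,
    stats,
    tools,
    utils,
    xml2,
    zip
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
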