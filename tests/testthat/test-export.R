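test_that("combined XML export round-trips the metadata exactly", {
  fx <- example_fixture(with_data = FALSE)
  doc <- export_xml(fx$meta, fx$scheme)
  expect_identical(xml2::xml_name(doc), "emeScheme")
  expect_identical(xml2::xml_attr(doc, "schemeVersion"), "0.9.9")
  expect_identical(read_metadata_xml(doc, fx$scheme), fx$meta)

  # through a file, too
  path <- tempfile(fileext = ".xml")
  export_xml(fx$meta, fx$scheme, path = path)
  expect_identical(read_metadata_xml(path, fx$scheme), fx$meta)
})

test_that("empty metadata over the template scheme exports a root with empty set elements", {
  s <- new_template_scheme()
  doc <- export_xml(empty_metadata(s), s, validate = FALSE)
  expect_identical(xml2::xml_name(doc), "dmdScheme")
  kids <- xml2::xml_children(doc)
  expect_identical(xml2::xml_name(kids), "Metadata")
  expect_length(xml2::xml_children(kids[[1]]), 0L)
})

test_that("export is gated on error-free validation", {
  error_faults <- list(c(VAL_NOT_ALLOWED = 1L), c(VAL_REQUIRED_MISSING = 1L),
                       c(CONS_DANGLING_REF = 1L), c(STRUCT_ROW_COUNT = 1L))
  for (faults in error_faults) {
    fx <- example_fixture(faults = faults, with_data = FALSE)
    expect_error(export_xml(fx$meta, fx$scheme), class = "mds_export_error",
                 label = names(faults))
    expect_error(export_xml_per_datafile(fx$meta, fx$scheme, tempfile()),
                 class = "mds_export_error", label = names(faults))
    expect_error(export_xml(fx$meta, fx$scheme), regexp = "1 error")
  }

  # notes and warnings do not block export
  soft_faults <- list(c(VAL_NOT_SUGGESTED = 2L), c(CONS_DUPLICATE_KEY = 1L),
                      c(STRUCT_UNKNOWN_SET = 1L))
  for (faults in soft_faults) {
    fx <- example_fixture(faults = faults, with_data = FALSE)
    expect_s3_class(export_xml(fx$meta, fx$scheme), "xml_document")
  }
})

test_that("per-data-file export writes one self-contained document per declared file", {
  fx <- example_fixture(with_data = FALSE)
  out <- tempfile()
  docs <- export_xml_per_datafile(fx$meta, fx$scheme, out)
  files <- fx$meta$tables$DataFiles$FileName
  expect_identical(sort(names(docs)), sort(files))
  expect_identical(sort(list.files(out)), sort(paste0(files, ".xml")))

  # experiment-level section byte-identical across documents
  experiment_bytes <- vapply(names(docs), function(f) {
    doc <- xml2::read_xml(file.path(out, paste0(f, ".xml")))
    xml2::xml_ns_strip(doc)
    as.character(xml2::xml_find_first(doc, "./Experiment"))
  }, "")
  expect_identical(length(unique(experiment_bytes)), 1L)

  # each file-scoped record appears in exactly one document
  for (set in c("DataFiles", "DataFileColumns")) {
    per_doc <- lapply(names(docs), function(f) {
      doc <- xml2::read_xml(file.path(out, paste0(f, ".xml")))
      xml2::xml_ns_strip(doc)
      vapply(xml2::xml_find_all(doc, sprintf("./%s/record", set)),
             as.character, "")
    })
    all_records <- unlist(per_doc)
    expect_identical(anyDuplicated(all_records), 0L)
  }
  # ... and all declared column records are accounted for
  n_cols <- sum(vapply(names(docs), function(f) {
    doc <- xml2::read_xml(file.path(out, paste0(f, ".xml")))
    xml2::xml_ns_strip(doc)
    length(xml2::xml_find_all(doc, "./DataFileColumns/record"))
  }, 0L))
  expect_identical(n_cols, nrow(fx$meta$tables$DataFileColumns))
})

test_that("records not tied to any data file are replicated into every document", {
  fx <- example_fixture(with_data = FALSE)
  out <- tempfile()
  docs <- export_xml_per_datafile(fx$meta, fx$scheme, out)
  for (f in names(docs)) {
    doc <- xml2::read_xml(file.path(out, paste0(f, ".xml")))
    xml2::xml_ns_strip(doc)
    expect_identical(length(xml2::xml_find_all(doc, "./Species/record")),
                     nrow(fx$meta$tables$Species))
  }
})

test_that("zero declared data files export to an empty mapping without error", {
  fx <- example_fixture(n_datafiles = 0, with_data = FALSE)
  docs <- export_xml_per_datafile(fx$meta, fx$scheme, tempfile())
  expect_length(docs, 0L)
})

test_that("foreign or malformed XML is rejected on read", {
  expect_error(read_metadata_xml("<not-closed"), class = "mds_format_error")
  expect_error(read_metadata_xml("<foreign><x/></foreign>"),
               class = "mds_format_error")
  fx <- example_fixture(with_data = FALSE)
  doc <- export_xml(fx$meta, fx$scheme)
  expect_error(read_metadata_xml(doc, tiny_scheme()), class = "mds_format_error")
})

test_that("the EML mapping stub reports coverage and dangling entries", {
  s <- tiny_scheme()
  all_paths <- c("Culture/SpeciesName", "Culture/Device", "Culture/Replicates",
                 "Culture/Volume_ml", "Sample/SampleID", "Sample/SpeciesName")

  none <- eml_mapping_stub(s)
  expect_false(any(none$mapped))

  full <- eml_mapping_stub(s, stats::setNames(paste0("eml/", all_paths), all_paths))
  expect_true(all(full$mapped))
  expect_length(attr(full, "dangling"), 0L)

  partial <- eml_mapping_stub(s, c("Culture/SpeciesName" = "eml/taxon",
                                   "Culture/Nonexistent" = "eml/x"))
  expect_identical(sum(partial$mapped), 1L)
  expect_identical(attr(partial, "dangling"), "Culture/Nonexistent")
})
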