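test_that("template workbooks have one sheet per property set plus the identity sheet", {
  wb <- tempfile(fileext = ".xlsx")
  write_template_workbook(new_template_scheme(), wb)
  expect_identical(readxl::excel_sheets(wb), c("_scheme", "Metadata"))

  wb2 <- tempfile(fileext = ".xlsx")
  write_template_workbook(make_example_scheme(), wb2)
  expect_length(readxl::excel_sheets(wb2), 8L)  # 7 sets + "_scheme"

  ill <- add_property(new_template_scheme(), "Metadata",
                      md_property("Bad", allowed = "a", suggested = "b"))
  expect_error(write_template_workbook(ill, tempfile(fileext = ".xlsx")),
               class = "mds_definition_error")
})

test_that("a fresh template workbook reads back as empty metadata", {
  s <- make_example_scheme()
  wb <- tempfile(fileext = ".xlsx")
  write_template_workbook(s, wb)
  meta <- read_metadata_workbook(wb)
  expect_identical(meta, empty_metadata(s))
})

test_that("filled workbooks round-trip the metadata exactly", {
  fx <- example_fixture(with_data = FALSE)
  wb <- tempfile(fileext = ".xlsx")
  write_filled_workbook(fx$scheme, fx$meta, wb)
  expect_identical(read_metadata_workbook(wb), fx$meta)
})

test_that("faulted metadata (extra sheets, extra and missing columns) survives the round trip", {
  faults <- c(STRUCT_UNKNOWN_SET = 1L, STRUCT_UNKNOWN_PROPERTY = 2L,
              STRUCT_MISSING_PROPERTY = 1L)
  fx <- example_fixture(faults = faults, with_data = FALSE)
  wb <- tempfile(fileext = ".xlsx")
  write_filled_workbook(fx$scheme, fx$meta, wb)
  back <- read_metadata_workbook(wb)
  expect_identical(back, fx$meta)
  expect_issues_equal(validate_all(back, fx$scheme), fx$expected)
})

test_that("reading trims whitespace and drops trailing all-empty rows", {
  s <- tiny_scheme()
  sheets <- mdscheme:::workbook_sheets(s)
  sheets$Culture <- rbind(sheets$Culture,
    c("  Tetrahymena thermophila ", " microscope", " 3 ", "0.5"),
    c("", "", "", ""))
  wb <- tempfile(fileext = ".xlsx")
  mdscheme:::write_xlsx_strings(sheets, wb)
  meta <- read_metadata_workbook(wb)
  expect_identical(nrow(meta$tables$Culture), 1L)
  expect_identical(meta$tables$Culture$SpeciesName, "Tetrahymena thermophila")
  expect_identical(meta$tables$Culture$Device, "microscope")
})

test_that("workbooks without an identity sheet are rejected as foreign", {
  wb <- tempfile(fileext = ".xlsx")
  mdscheme:::write_xlsx_strings(list(Sheet1 = matrix("x", 1, 1)), wb)
  expect_error(read_metadata_workbook(wb), class = "mds_format_error")
  expect_error(detect_scheme_id(wb), class = "mds_format_error")
  expect_error(read_metadata_workbook(tempfile(fileext = ".xlsx")),
               class = "mds_io_error")

  corrupt <- tempfile(fileext = ".xlsx")
  mdscheme:::write_xlsx_strings(list("_scheme" = matrix("junk", 1, 1)), corrupt)
  expect_error(detect_scheme_id(corrupt), class = "mds_format_error")
})

test_that("detect_scheme_id reads the identity without the data sheets", {
  fx <- example_fixture(with_data = FALSE)
  wb <- tempfile(fileext = ".xlsx")
  write_filled_workbook(fx$scheme, fx$meta, wb)
  expect_identical(detect_scheme_id(wb), c(name = "emeScheme", version = "0.9.9"))

  tmpl <- tempfile(fileext = ".xlsx")
  write_template_workbook(new_template_scheme("dmdScheme", "0.9.9"), tmpl)
  expect_identical(detect_scheme_id(tmpl), c(name = "dmdScheme", version = "0.9.9"))
})

test_that("workbook writing is deterministic in content and bytes", {
  s <- make_example_scheme()
  wb1 <- tempfile(fileext = ".xlsx"); wb2 <- tempfile(fileext = ".xlsx")
  write_template_workbook(s, wb1)
  write_template_workbook(s, wb2)
  expect_identical(read_file_bytes(wb1), read_file_bytes(wb2))
})

test_that("the CSV-directory twin round-trips identically to the workbook", {
  fx <- example_fixture(with_data = FALSE)
  wb <- tempfile(fileext = ".xlsx")
  write_filled_workbook(fx$scheme, fx$meta, wb)
  from_wb <- read_metadata_workbook(wb)

  dir <- tempfile()
  write_metadata_csvdir(fx$meta, dir)
  from_csv <- read_metadata_csvdir(dir)
  expect_identical(from_csv, from_wb)
  expect_identical(read_metadata_workbook(dir), from_csv)
  expect_identical(detect_scheme_id(dir), c(name = "emeScheme", version = "0.9.9"))

  expect_error(read_metadata_csvdir(tempfile()), class = "mds_io_error")
})
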