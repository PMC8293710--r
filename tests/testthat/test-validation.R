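test_that("clean fixture metadata validates with zero issues at every stage", {
  fx <- example_fixture()
  expect_identical(nrow(validate_structure(fx$meta, fx$scheme)), 0L)
  expect_identical(nrow(validate_values(fx$meta, fx$scheme)), 0L)
  expect_identical(nrow(validate_consistency(fx$meta, fx$scheme)), 0L)
  expect_identical(nrow(validate_data_files(fx$meta, fx$scheme, fx$data_dir)), 0L)
  report <- validate_all(fx$meta, fx$scheme, data_dir = fx$data_dir)
  expect_identical(report$worst, "success")
  expect_identical(nrow(report$issues), 0L)
})

test_that("structural deviations get the documented code and severity", {
  fx <- example_fixture(with_data = FALSE)
  meta <- fx$meta

  dropped <- meta
  dropped$tables$Species <- NULL
  iss <- validate_structure(dropped, fx$scheme)
  expect_identical(iss$code, "STRUCT_MISSING_SET")
  expect_identical(iss$severity, "error")
  expect_identical(iss$property_set, "Species")

  extra_col <- meta
  extra_col$tables$Species$Color <- "green"
  iss <- validate_structure(extra_col, fx$scheme)
  expect_identical(iss$code, "STRUCT_UNKNOWN_PROPERTY")
  expect_identical(iss$severity, "warning")

  wrong_version <- meta
  wrong_version$scheme_version <- "9.9.9"
  iss <- validate_structure(wrong_version, fx$scheme)
  expect_identical(iss$code, "STRUCT_SCHEME_MISMATCH")

  no_rows <- meta
  no_rows$tables$Experiment <- meta$tables$Experiment[0, , drop = FALSE]
  iss <- validate_structure(no_rows, fx$scheme)
  expect_identical(iss$code, "STRUCT_ROW_COUNT")
  two_rows <- meta
  two_rows$tables$Experiment <- rbind(meta$tables$Experiment, meta$tables$Experiment)
  expect_identical(validate_structure(two_rows, fx$scheme)$code, "STRUCT_ROW_COUNT")
})

test_that("vocabulary semantics: closed lists error, open lists only note", {
  s <- tiny_scheme()
  not_allowed <- tiny_meta(culture = list(SpeciesName = "Paramecium caudatum"))
  iss <- validate_values(not_allowed, s)
  expect_identical(nrow(iss), 1L)
  expect_identical(iss$code, "VAL_NOT_ALLOWED")
  expect_identical(iss$severity, "error")

  odd_device <- tiny_meta(culture = list(Device = "flowcytometer2"))
  iss <- validate_values(odd_device, s)
  expect_identical(nrow(iss), 1L)
  expect_identical(iss$code, "VAL_NOT_SUGGESTED")
  expect_identical(iss$severity, "note")
})

test_that("required, type and range rules each flag exactly the offending cell", {
  s <- tiny_scheme()

  iss <- validate_values(tiny_meta(sample = list(SampleID = "", SpeciesName = "")), s)
  expect_identical(nrow(iss), 1L)
  expect_identical(iss$code, "VAL_REQUIRED_MISSING")
  expect_identical(iss$severity, "error")
  expect_identical(iss$property, "SampleID")

  iss <- validate_values(tiny_meta(culture = list(Replicates = "3.7")), s)
  expect_identical(iss$code, "VAL_TYPE")
  expect_identical(iss$severity, "error")

  iss <- validate_values(tiny_meta(culture = list(Volume_ml = "12.0")), s)
  expect_identical(iss$code, "VAL_RANGE")
  expect_identical(iss$severity, "error")

  expect_identical(nrow(validate_values(tiny_meta(), s)), 0L)
})

test_that("cross-references must resolve and keys must not repeat", {
  s <- tiny_scheme()
  dangling <- tiny_meta(sample = list(
    SampleID = c("S1", "S2"),
    SpeciesName = c("Tetrahymena thermophila", "Didinium nasutum")))
  iss <- validate_consistency(dangling, s)
  expect_identical(nrow(iss), 1L)
  expect_identical(iss$code, "CONS_DANGLING_REF")
  expect_identical(iss$row, 2L)

  dup <- tiny_meta(sample = list(SampleID = c("S1", "S1"),
                                 SpeciesName = rep("Colpidium striatum", 2)))
  dup$tables$Culture$SpeciesName <- "Colpidium striatum"
  iss <- validate_consistency(dup, s)
  expect_identical(iss$code, "CONS_DUPLICATE_KEY")
  expect_identical(iss$severity, "warning")
  expect_identical(iss$row, 2L)
})

test_that("a data file assigned two measurement rows is an error", {
  fx <- example_fixture(faults = c(CONS_MULTIPLE_METHODS = 1L), with_data = FALSE)
  iss <- validate_consistency(fx$meta, fx$scheme)
  expect_identical(iss$code, "CONS_MULTIPLE_METHODS")
  expect_identical(iss$severity, "error")
  expect_issues_equal(validate_all(fx$meta, fx$scheme), fx$expected)
})

test_that("data-file validation compares declarations against files on disk", {
  fx <- example_fixture()
  dd <- fx$data_dir

  # renamed header column: one missing declared column + one undeclared one
  f <- file.path(dd, "counts_01.csv")
  tab <- utils::read.csv(f, colClasses = "character", check.names = FALSE)
  names(tab)[names(tab) == "abundance"] <- "abund"
  utils::write.csv(tab, f, row.names = FALSE)
  iss <- validate_data_files(fx$meta, fx$scheme, dd)
  expect_identical(sort(iss$code), c("DATA_COLUMN_MISSING", "DATA_COLUMN_UNDECLARED"))
  expect_identical(sort(iss$severity), c("error", "warning"))

  # deleted declared file
  file.remove(file.path(dd, "counts_02.csv"))
  iss <- validate_data_files(fx$meta, fx$scheme, dd)
  expect_identical(sum(iss$code == "DATA_FILE_MISSING"), 1L)

  # a non-conforming value in a typed column
  f3 <- file.path(dd, "counts_03.csv")
  tab <- utils::read.csv(f3, colClasses = "character", check.names = FALSE)
  tab$day[2] <- "noon"
  utils::write.csv(tab, f3, row.names = FALSE)
  iss <- validate_data_files(fx$meta, fx$scheme, dd)
  expect_identical(sum(iss$code == "DATA_COLUMN_TYPE"), 1L)

  expect_error(validate_data_files(fx$meta, fx$scheme, tempfile()),
               class = "mds_io_error")
})

test_that("error-level structural problems suppress downstream checks for the affected table only", {
  fx <- example_fixture(with_data = FALSE)
  meta <- fx$meta
  # remove a required column: one structural error, no cascading value errors
  meta$tables$Species$CommonLabel <- NULL
  # and an unrelated value fault elsewhere still surfaces
  meta$tables$Treatment$Replicates[1] <- "many"
  report <- validate_all(meta, fx$scheme)
  expect_identical(sort(report$issues$code),
                   c("STRUCT_MISSING_PROPERTY", "VAL_TYPE"))

  # deleting the referenced set silences the reference check instead of
  # producing spurious dangling references
  meta2 <- fx$meta
  meta2$tables$Species <- NULL
  report2 <- validate_all(meta2, fx$scheme)
  expect_identical(report2$issues$code, "STRUCT_MISSING_SET")
})

test_that("validation is idempotent and stages are independent", {
  faults <- c(VAL_NOT_ALLOWED = 1L, CONS_DANGLING_REF = 1L)
  fx <- example_fixture(faults = faults, with_data = FALSE)
  r1 <- validate_all(fx$meta, fx$scheme)
  r2 <- validate_all(fx$meta, fx$scheme)
  expect_identical(r1$issues, r2$issues)
  expect_identical(r1$worst, r2$worst)
  # disjoint seeded faults are additive, never masking
  expect_issues_equal(r1, fx$expected)
  expect_identical(nrow(r1$issues), 2L)
})
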