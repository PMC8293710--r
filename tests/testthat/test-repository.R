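local_repo <- function(seed = 1) {
  repo <- tempfile("repo")
  make_fixture_repository(repo, seed = seed)
  repo
}

test_that("packing produces the named archive with a content-faithful manifest", {
  s <- make_example_scheme()
  ex <- make_filled_metadata(s, seed = 3)
  out <- tempfile()
  pkg <- pack_scheme(s, examples = list(filled = ex$meta), out_dir = out)
  expect_identical(basename(pkg$path), "emeScheme_0.9.9.zip")
  expect_true(file.exists(pkg$path))
  members <- zip::zip_list(pkg$path)$filename
  expect_true(all(c("scheme.json", "template.xlsx", "examples/filled.xlsx",
                    "manifest.json") %in% members))
})

test_that("examples with validation errors refuse to pack", {
  s <- make_example_scheme()
  bad <- make_filled_metadata(s, faults = c(VAL_NOT_ALLOWED = 1L), seed = 3)
  expect_error(pack_scheme(s, examples = list(bad = bad$meta), out_dir = tempfile()),
               class = "mds_definition_error")
  # note-level findings do not block packaging
  noted <- make_filled_metadata(s, faults = c(VAL_NOT_SUGGESTED = 1L), seed = 3)
  expect_s3_class(pack_scheme(s, examples = list(noted = noted$meta),
                              out_dir = tempfile()), "md_scheme_package")
})

test_that("listing sorts by name then descending semantic version", {
  repo <- local_repo()
  entries <- list_schemes(repo)
  expect_identical(entries$name, c("emeScheme", "emeScheme"))
  expect_identical(entries$version, c("1.1.7", "0.9.9"))

  empty <- tempfile(); dir.create(empty)
  build_repo_index(empty)
  expect_identical(nrow(list_schemes(empty)), 0L)

  corrupt <- tempfile(); dir.create(corrupt)
  writeLines("{not json", file.path(corrupt, "index.json"))
  expect_error(list_schemes(corrupt), class = "mds_repository_error")
  expect_error(list_schemes(tempfile()), class = "mds_repository_error")
})

test_that("install round-trips the packed scheme and respects 'latest' semver", {
  repo <- local_repo()
  inst <- install_scheme(repo, "emeScheme", "0.9.9", dest_dir = tempfile())
  expect_identical(inst$scheme, make_example_scheme())

  latest <- install_scheme(repo, "emeScheme", "latest", dest_dir = tempfile())
  expect_identical(latest$scheme$version, "1.1.7")

  expect_error(install_scheme(repo, "noSuchScheme"), class = "mds_repository_error")
  expect_error(install_scheme(repo, "emeScheme", "3.0.0"),
               class = "mds_repository_error")
})

test_that("archive tampering is detected by the checksum", {
  repo <- local_repo()
  archive <- file.path(repo, "emeScheme_0.9.9.zip")
  bytes <- read_file_bytes(archive)
  bytes[length(bytes) - 10L] <- as.raw(bitwXor(as.integer(bytes[length(bytes) - 10L]), 255L))
  writeBin(bytes, archive)
  expect_error(install_scheme(repo, "emeScheme", "0.9.9", dest_dir = tempfile()),
               class = "mds_integrity_error")
})

test_that("install never mutates the repository and repeated installs agree", {
  repo <- local_repo()
  before <- lapply(sort(list.files(repo, full.names = TRUE)), read_file_bytes)
  i1 <- install_scheme(repo, "emeScheme", "latest", dest_dir = tempfile())
  i2 <- install_scheme(repo, "emeScheme", "latest", dest_dir = tempfile())
  after <- lapply(sort(list.files(repo, full.names = TRUE)), read_file_bytes)
  expect_identical(before, after)
  expect_identical(i1$scheme, i2$scheme)
  expect_identical(i1$files, i2$files)
})

test_that("pack -> install -> pack is a fixed point", {
  repo <- local_repo()
  inst <- install_scheme(repo, "emeScheme", "0.9.9", dest_dir = tempfile())
  meta <- read_metadata_workbook(file.path(inst$dir, "examples", "filled.xlsx"))
  repacked <- pack_scheme(inst$scheme, examples = list(filled = meta),
                          out_dir = tempfile())
  # byte-identical archives imply equal manifests and equal member content
  expect_identical(read_file_bytes(repacked$path),
                   read_file_bytes(file.path(repo, "emeScheme_0.9.9.zip")))
  original <- mdscheme:::read_package_manifest(file.path(repo, "emeScheme_0.9.9.zip"))
  expect_identical(repacked$manifest$contentChecksum, original$contentChecksum)
})
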