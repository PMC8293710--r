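# Shared fixtures and comparison helpers.

# Canonical form for comparing issue sets as multisets: fixed columns,
# stable ordering, no rownames.
norm_issues <- function(df) {
  cols <- c("code", "severity", "property_set", "property", "row")
  df <- as.data.frame(df)[, cols]
  df <- df[order(df$code, df$property_set, df$property, df$row, df$severity), ]
  rownames(df) <- NULL
  df
}

expect_issues_equal <- function(report, expected) {
  expect_identical(norm_issues(report$issues), norm_issues(expected))
}

# A two-set scheme small enough to reason about by hand, with one example
# of every value rule: closed vocabulary, open vocabulary, required field,
# integer type, bounded real.
tiny_scheme <- function() {
  md_scheme(
    name = "tinyScheme", version = "1.0.0",
    property_sets = list(
      md_property_set("Culture", cardinality = "exactly-one-row", properties = list(
        md_property("SpeciesName", "character", required = TRUE,
                    allowed = c("Tetrahymena thermophila", "Colpidium striatum")),
        md_property("Device", "character",
                    suggested = c("flowcytometer", "microscope")),
        md_property("Replicates", "integer"),
        md_property("Volume_ml", "real", min_value = 0, max_value = 10)
      )),
      md_property_set("Sample", properties = list(
        md_property("SampleID", "character", required = TRUE),
        md_property("SpeciesName", "character",
                    refers_to = c("Culture", "SpeciesName"))
      ))
    )
  )
}

tiny_meta <- function(culture = list(), sample = list()) {
  defaults <- list(SpeciesName = "Tetrahymena thermophila",
                   Device = "flowcytometer", Replicates = "3", Volume_ml = "0.5")
  defaults[names(culture)] <- culture
  culture_df <- as.data.frame(defaults, stringsAsFactors = FALSE)
  sample_df <- if (length(sample) > 0) as.data.frame(sample, stringsAsFactors = FALSE)
    else data.frame(SampleID = "S1", SpeciesName = "Tetrahymena thermophila",
                    stringsAsFactors = FALSE)
  md_metadata("tinyScheme", "1.0.0",
              list(Culture = culture_df, Sample = sample_df))
}

# Clean example fixture with its toy data files in a temp dir.
example_fixture <- function(n_species = 3, n_datafiles = 3, faults = NULL,
                            seed = 1, with_data = TRUE) {
  scheme <- make_example_scheme()
  fx <- make_filled_metadata(scheme, n_species, n_datafiles,
                             faults = faults, seed = seed)
  out <- list(scheme = scheme, meta = fx$meta, expected = fx$expected)
  if (with_data) {
    out$data_dir <- withr::local_tempdir(.local_envir = parent.frame())
    td <- make_toy_datafiles(fx$meta, out$data_dir, faults = faults, seed = seed)
    out$expected_data <- td$expected
  }
  out
}

read_file_bytes <- function(path) readBin(path, "raw", file.info(path)$size)

# Render a report without its timestamp line (reports are equal up to it).
render_stable_text <- function(doc) {
  paste(grep("Validated", strsplit(doc, "\n")[[1]],
             invert = TRUE, value = TRUE, fixed = TRUE), collapse = "\n")
}

render_stable <- function(report, format = "markdown") {
  render_stable_text(render_report(report, format))
}
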