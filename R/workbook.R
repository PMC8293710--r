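# Entry-workbook I/O.
#
# Layout: each property set is one worksheet named after the set, preceded by
# an identity sheet "_scheme" holding the scheme name, version and per-sheet
# cardinality. Property sheets carry four header rows -- property names,
# descriptions, "type[:required]" markers, and the vocabulary rendered as
# "allowed:a|b" or "suggested:a|b" -- with data starting in row 5. A
# diff-friendly plain-text twin (one CSV per sheet plus a JSON identity file)
# round-trips identically.

wb_header_rows <- 4L
wb_id_sheet <- "_scheme"

header_block <- function(scheme, set_name, col_names) {
  ps <- get_set(scheme, set_name)
  block <- matrix("", nrow = wb_header_rows, ncol = length(col_names))
  block[1, ] <- col_names
  if (is.null(ps)) return(block)
  for (j in seq_along(col_names)) {
    p <- get_prop(ps, col_names[j])
    if (is.null(p)) next
    block[2, j] <- p$description
    block[3, j] <- paste0(p$type, if (p$required) ":required" else "")
    if (length(p$allowed) > 0)
      block[4, j] <- paste0("allowed:", paste(p$allowed, collapse = "|"))
    else if (length(p$suggested) > 0)
      block[4, j] <- paste0("suggested:", paste(p$suggested, collapse = "|"))
  }
  block
}

id_sheet_matrix <- function(scheme) {
  rows <- rbind(
    c("name", scheme$name),
    c("version", scheme$version)
  )
  for (ps in scheme$property_sets)
    rows <- rbind(rows, c(paste0("cardinality:", ps$name), ps$cardinality))
  rows
}

workbook_sheets <- function(scheme, meta = NULL) {
  tables <- if (is.null(meta)) empty_metadata(scheme)$tables else meta$tables
  declared <- set_names_of(scheme)
  order <- unique(c(intersect(declared, names(tables)),
                    setdiff(declared, names(tables)),
                    setdiff(names(tables), declared)))
  sheets <- list()
  sheets[[wb_id_sheet]] <- id_sheet_matrix(scheme)
  for (nm in order) {
    tab <- tables[[nm]]
    if (is.null(tab)) {
      tab <- empty_metadata(scheme)$tables[[nm]]
    }
    cols <- names(tab)
    block <- header_block(scheme, nm, cols)
    if (nrow(tab) > 0) block <- rbind(block, as.matrix(tab))
    dimnames(block) <- NULL
    sheets[[nm]] <- block
  }
  sheets
}

#' Write the empty entry workbook for a scheme
#'
#' Generates the workbook researchers fill in: one sheet per property set
#' with the four-row header described in the package vignette, plus the
#' `_scheme` identity sheet. Cell content is deterministic: writing the same
#' scheme twice yields byte-identical files.
#'
#' @param scheme An [md_scheme()] passing [check_scheme_definition()].
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_template_workbook <- function(scheme, path) {
  stopifnot(inherits(scheme, "md_scheme"))
  assert_scheme_ok(scheme)
  write_xlsx_strings(workbook_sheets(scheme), path)
}

#' Write a filled entry workbook
#'
#' Same layout as [write_template_workbook()] with the metadata rows
#' appended below the headers. Tables or columns unknown to the scheme are
#' written too (with name-only headers) so that validation can flag them
#' after a round trip.
#'
#' @param scheme An [md_scheme()] passing [check_scheme_definition()].
#' @param meta An [md_metadata()].
#' @param path Output `.xlsx` path.
#' @return `path`, invisibly.
#' @export
write_filled_workbook <- function(scheme, meta, path) {
  stopifnot(inherits(scheme, "md_scheme"), inherits(meta, "md_metadata"))
  assert_scheme_ok(scheme)
  write_xlsx_strings(workbook_sheets(scheme, meta), path)
}

strip_table <- function(df) {
  df <- normalize_table(df)
  if (ncol(df) > 0) df[] <- lapply(df, trimws)
  # Drop trailing all-empty rows (spreadsheet users leave ragged tails).
  if (nrow(df) > 0) {
    keep <- rev(cumprod(rev(apply(df == "", 1, all))) == 0)
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

parse_id_sheet <- function(sheet, path) {
  if (is.null(sheet) || ncol(sheet) < 2)
    abort_format(sprintf("workbook '%s' has a corrupted '%s' sheet", path, wb_id_sheet))
  keys <- trimws(sheet[[1]]); vals <- trimws(sheet[[2]])
  name <- vals[match("name", keys)]
  version <- vals[match("version", keys)]
  if (is.na(name) || is.na(version) || !nzchar(name) || !nzchar(version))
    abort_format(sprintf("workbook '%s' has a corrupted '%s' sheet", path, wb_id_sheet))
  c(name = name, version = version)
}

#' Read a filled entry workbook
#'
#' Reads every data sheet verbatim as strings: row 1 supplies the column
#' names, rows 2--4 (descriptions, types, vocabularies) are layout and are
#' skipped, data starts in row 5. Values are whitespace-trimmed, trailing
#' all-empty rows are dropped, and the empty string means missing. No
#' semantic checking happens here; unknown sheets and columns are retained
#' for [validate_structure()] to report.
#'
#' @param path Path to an `.xlsx` workbook (or a CSV directory written by
#'   [write_metadata_csvdir()]).
#' @return An [md_metadata()] identified by the workbook's `_scheme` sheet.
#' @export
read_metadata_workbook <- function(path) {
  if (dir.exists(path)) return(read_metadata_csvdir(path))
  sheets <- read_xlsx_strings(path)
  if (!wb_id_sheet %in% names(sheets))
    abort_format(sprintf("workbook '%s' has no '%s' sheet: not a metadata workbook",
                         path, wb_id_sheet))
  id <- parse_id_sheet(sheets[[wb_id_sheet]], path)
  data_sheets <- sheets[setdiff(names(sheets), wb_id_sheet)]
  tables <- lapply(data_sheets, function(df) {
    df <- normalize_table(df)
    if (nrow(df) == 0 || ncol(df) == 0)
      return(normalize_table(data.frame()))
    header <- trimws(unlist(df[1, ], use.names = FALSE))
    keep <- nzchar(header)
    if (!any(keep)) return(normalize_table(data.frame()))
    body <- df[-seq_len(min(wb_header_rows, nrow(df))), keep, drop = FALSE]
    names(body) <- header[keep]
    strip_table(body)
  })
  md_metadata(id[["name"]], id[["version"]], tables)
}

#' Identify the scheme a workbook was made for
#'
#' Reads only the `_scheme` identity sheet, without loading the data sheets;
#' used to auto-select the matching installed scheme.
#'
#' @inheritParams read_metadata_workbook
#' @return Named character vector `c(name =, version =)`.
#' @export
detect_scheme_id <- function(path) {
  if (dir.exists(path)) {
    idf <- file.path(path, "_scheme.json")
    if (!file.exists(idf))
      abort_format(sprintf("'%s' has no _scheme.json identity file", path))
    id <- jsonlite::fromJSON(idf)
    if (is.null(id$name) || is.null(id$version))
      abort_format(sprintf("'%s' has a corrupted _scheme.json", path))
    return(c(name = id$name, version = id$version))
  }
  if (!file.exists(path)) abort_io(sprintf("cannot read workbook '%s'", path))
  sheet_names <- readxl::excel_sheets(path)
  if (!wb_id_sheet %in% sheet_names)
    abort_format(sprintf("workbook '%s' has no '%s' sheet: not a metadata workbook",
                         path, wb_id_sheet))
  df <- suppressMessages(readxl::read_xlsx(path, sheet = wb_id_sheet,
                                           col_names = FALSE, col_types = "text",
                                           .name_repair = "minimal"))
  parse_id_sheet(normalize_table(df), path)
}

# ---- plain-text twin ------------------------------------------------------

#' Write metadata as a CSV directory
#'
#' Diff-friendly twin of the workbook: one RFC-4180 CSV per property set
#' plus `_scheme.json` recording the scheme id and table order. Reading it
#' back with [read_metadata_workbook()] (or [read_metadata_csvdir()])
#' gives a metadata set equal to the one read from the workbook form.
#'
#' @param meta An [md_metadata()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_metadata_csvdir <- function(meta, dir) {
  stopifnot(inherits(meta, "md_metadata"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- list(name = meta$scheme_name, version = meta$scheme_version,
             tables = I(names(meta$tables)))
  writeLines(jsonlite::toJSON(id, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "_scheme.json"), useBytes = TRUE)
  for (nm in names(meta$tables)) {
    utils::write.csv(meta$tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read metadata from a CSV directory
#'
#' @param dir Directory written by [write_metadata_csvdir()].
#' @return An [md_metadata()].
#' @export
read_metadata_csvdir <- function(dir) {
  if (!dir.exists(dir)) abort_io(sprintf("'%s' is not a directory", dir))
  idf <- file.path(dir, "_scheme.json")
  if (!file.exists(idf))
    abort_format(sprintf("'%s' has no _scheme.json identity file", dir))
  id <- jsonlite::fromJSON(idf)
  if (is.null(id$name) || is.null(id$version))
    abort_format(sprintf("'%s' has a corrupted _scheme.json", dir))
  table_names <- as.character(id$tables %||% character())
  tables <- lapply(table_names, function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) abort_format(sprintf("table file '%s' is missing", f))
    strip_table(utils::read.csv(f, colClasses = "character", check.names = FALSE,
                                na.strings = character()))
  })
  names(tables) <- table_names
  md_metadata(id$name, id$version, tables)
}
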