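# Minimal Office Open XML workbook writer.
#
# The toolkit only ever needs plain text cells (all metadata values are raw
# strings until validation types them), so worksheets are emitted with
# inline-string cells and no styling, shared-string table or formulas.
# Reading filled workbooks back goes through readxl.

col_letter <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1L) %% 26L
    s <- paste0(LETTERS[r + 1L], s)
    j <- (j - 1L) %/% 26L
  }
  s
}

sheet_to_xml <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  rows <- character(nr)
  for (i in seq_len(nr)) {
    cells <- character(0)
    for (j in seq_len(nc)) {
      v <- mat[i, j]
      if (is.na(v) || !nzchar(v)) next
      cells <- c(cells, sprintf(
        '<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
        col_letter(j), i, xml_escape(v)))
    }
    rows[i] <- sprintf('<row r="%d">%s</row>', i, paste0(cells, collapse = ""))
  }
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", paste0(rows, collapse = ""), "</sheetData></worksheet>")
}

# sheets: named list of character matrices (may have 0 rows).
write_xlsx_strings <- function(sheets, path) {
  stopifnot(length(sheets) > 0, !is.null(names(sheets)))
  dir <- tempfile("mds_xlsx_")
  dir.create(file.path(dir, "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "worksheets"), recursive = TRUE)
  on.exit(unlink(dir, recursive = TRUE))
  n <- length(sheets)

  content_types <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste0(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                   seq_len(n)), collapse = ""),
    "</Types>")
  root_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>")
  workbook <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"',
    ' xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    paste0(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                   xml_escape(names(sheets)), seq_len(n), seq_len(n)), collapse = ""),
    "</sheets></workbook>")
  wb_rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste0(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                   seq_len(n), seq_len(n)), collapse = ""),
    "</Relationships>")

  writeLines(content_types, file.path(dir, "[Content_Types].xml"), useBytes = TRUE)
  writeLines(root_rels, file.path(dir, "_rels", ".rels"), useBytes = TRUE)
  writeLines(workbook, file.path(dir, "xl", "workbook.xml"), useBytes = TRUE)
  writeLines(wb_rels, file.path(dir, "xl", "_rels", "workbook.xml.rels"), useBytes = TRUE)
  for (k in seq_len(n)) {
    writeLines(sheet_to_xml(as.matrix(sheets[[k]])),
               file.path(dir, "xl", "worksheets", sprintf("sheet%d.xml", k)),
               useBytes = TRUE)
  }

  out_dir <- dirname(path)
  if (!dir.exists(out_dir)) abort_io(sprintf("directory '%s' does not exist", out_dir))
  files <- c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
             "xl/_rels/workbook.xml.rels",
             sprintf("xl/worksheets/sheet%d.xml", seq_len(n)))
  zip_deterministic(path, files, dir)
  invisible(path)
}

# All sheets of a workbook as character data frames (no header interpretation,
# NA -> "", whitespace trimmed by readxl).
read_xlsx_strings <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read workbook '%s'", path))
  sheet_names <- tryCatch(readxl::excel_sheets(path),
                          error = function(e) abort_io(sprintf("cannot read workbook '%s': %s", path, conditionMessage(e))))
  out <- lapply(sheet_names, function(s) {
    df <- suppressMessages(readxl::read_xlsx(
      path, sheet = s, col_names = FALSE, col_types = "text",
      .name_repair = "minimal"))
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (ncol(df) > 0) df[] <- lapply(df, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    })
    df
  })
  names(out) <- sheet_names
  out
}
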