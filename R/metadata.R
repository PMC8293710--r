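# Filled metadata: raw string tables tied to a scheme name and version.
# Values stay verbatim strings until validation or export types them;
# the empty string is the missing value.

normalize_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (ncol(df) > 0) {
    df[] <- lapply(df, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    })
  }
  rownames(df) <- NULL
  df
}

#' Construct a metadata set
#'
#' A metadata set holds the filled content of one entry workbook: one raw
#' string table per property set, keyed by property set name, plus the name
#' and version of the scheme it claims to follow. Whether the tables
#' actually conform to that scheme is the job of [validate_all()], not of
#' this constructor.
#'
#' @param scheme_name,scheme_version Identifiers of the declaring scheme.
#' @param tables Named list of data frames; all values are coerced to
#'   character and `NA` becomes `""` (missing).
#' @return An object of class `md_metadata`.
#' @export
md_metadata <- function(scheme_name, scheme_version, tables = list()) {
  if (!is_string(scheme_name) || !is_string(scheme_version))
    abort_definition("scheme_name and scheme_version must be single strings")
  if (length(tables) > 0 && is.null(names(tables)))
    abort_definition("tables must be a named list")
  structure(list(
    scheme_name = scheme_name, scheme_version = scheme_version,
    tables = lapply(tables, normalize_table)
  ), class = "md_metadata")
}

#' @export
print.md_metadata <- function(x, ...) {
  cat(sprintf("<md_metadata> for scheme %s_%s\n", x$scheme_name, x$scheme_version))
  for (nm in names(x$tables))
    cat(sprintf("  %s: %d row(s), %d column(s)\n", nm,
                nrow(x$tables[[nm]]), ncol(x$tables[[nm]])))
  invisible(x)
}

#' Empty metadata over a scheme
#'
#' One zero-row table per property set, columns in scheme order. The shape a
#' freshly written template workbook reads back as.
#'
#' @param scheme An [md_scheme()].
#' @return An [md_metadata()] with empty tables.
#' @export
empty_metadata <- function(scheme) {
  stopifnot(inherits(scheme, "md_scheme"))
  tables <- lapply(scheme$property_sets, function(ps) {
    cols <- stats::setNames(rep(list(character(0)), length(ps$properties)),
                            prop_names_of(ps))
    do.call(data.frame, c(cols, list(stringsAsFactors = FALSE, check.names = FALSE)))
  })
  names(tables) <- set_names_of(scheme)
  md_metadata(scheme$name, scheme$version, tables)
}
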