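# Three-stage validation engine.
#
# Stage "structure" compares the metadata tables against the scheme's
# property sets; stage "values" types every cell and checks vocabularies and
# ranges; stage "consistency" resolves cross-references, duplicate keys and
# the one-measurement-per-data-file rule; stage "data" compares the declared
# data files and columns against the actual files on disk. Every finding is
# an issue with a stable rule code and a severity from
# error > warning > note; findings are returned, never raised.

severity_rank <- c(note = 1L, warning = 2L, error = 3L)

rule_table <- function() {
  reg <- rbind(
    c("STRUCT_SCHEME_MISMATCH", "error",   "structure",   "metadata declares a different scheme name or version"),
    c("STRUCT_MISSING_SET",     "error",   "structure",   "a property set of the scheme has no table in the metadata"),
    c("STRUCT_UNKNOWN_SET",     "warning", "structure",   "the metadata carries a table unknown to the scheme"),
    c("STRUCT_MISSING_PROPERTY","error",   "structure",   "a declared property has no column in the table"),
    c("STRUCT_UNKNOWN_PROPERTY","warning", "structure",   "a table carries a column unknown to the scheme"),
    c("STRUCT_ROW_COUNT",       "error",   "structure",   "an exactly-one-row set does not have exactly one row"),
    c("VAL_REQUIRED_MISSING",   "error",   "values",      "a required cell is empty"),
    c("VAL_TYPE",               "error",   "values",      "a value does not parse under the declared type"),
    c("VAL_NOT_ALLOWED",        "error",   "values",      "a value is not in the closed (allowed) vocabulary"),
    c("VAL_NOT_SUGGESTED",      "note",    "values",      "a value is not in the open (suggested) vocabulary"),
    c("VAL_RANGE",              "error",   "values",      "a numeric value lies outside its declared range"),
    c("CONS_DANGLING_REF",      "error",   "consistency", "a cross-referencing value has no matching row in the referenced set"),
    c("CONS_DUPLICATE_KEY",     "warning", "consistency", "two rows of a set share the value of its first (key) property"),
    c("CONS_MULTIPLE_METHODS",  "error",   "consistency", "a data file is assigned more than one measurement/extraction row"),
    c("DATA_FILE_MISSING",      "error",   "data",        "a declared data file is absent from the data directory"),
    c("DATA_FILE_UNDECLARED",   "warning", "data",        "a file in the data directory is not declared in the metadata"),
    c("DATA_COLUMN_MISSING",    "error",   "data",        "a declared column is absent from the data file header"),
    c("DATA_COLUMN_UNDECLARED", "warning", "data",        "a data file header column is not declared in the metadata"),
    c("DATA_COLUMN_TYPE",       "error",   "data",        "a data file column holds values violating its declared type")
  )
  data.frame(code = reg[, 1], severity = reg[, 2], stage = reg[, 3],
             description = reg[, 4], stringsAsFactors = FALSE)
}

#' The validation rule registry
#'
#' Every issue a validator can emit carries one of these stable codes, at
#' the fixed severity listed here, so reports are machine-checkable.
#'
#' @return Data frame with columns `code`, `severity`, `stage`,
#'   `description`.
#' @export
rule_registry <- function() rule_table()

rule_severity <- function(code) {
  reg <- rule_table()
  s <- reg$severity[match(code, reg$code)]
  if (any(is.na(s))) abort_definition(sprintf("unknown rule code '%s'", code[is.na(s)][1]))
  s
}

no_issues <- function() {
  data.frame(severity = character(), code = character(),
             property_set = character(), property = character(),
             row = integer(), message = character(), stringsAsFactors = FALSE)
}

issue <- function(code, set = "", property = "", row = 0L, message = "") {
  data.frame(severity = rule_severity(code), code = code,
             property_set = set, property = property, row = as.integer(row),
             message = message, stringsAsFactors = FALSE)
}

bind_issues <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0) return(no_issues())
  do.call(rbind, lst)
}

#' Validate metadata structure against its scheme
#'
#' Checks the table layout only: matching scheme id, a table per property
#' set (missing: error; extra: warning), a column per property (missing:
#' error; extra: warning), and exactly one data row for exactly-one-row
#' sets. Cell content is left to [validate_values()].
#'
#' @param meta An [md_metadata()].
#' @param scheme An [md_scheme()] passing [check_scheme_definition()].
#' @return Issue data frame (see [rule_registry()]); zero rows when clean.
#' @export
validate_structure <- function(meta, scheme) {
  stopifnot(inherits(meta, "md_metadata"), inherits(scheme, "md_scheme"))
  assert_scheme_ok(scheme)
  out <- list()
  if (!identical(meta$scheme_name, scheme$name) ||
      !identical(meta$scheme_version, scheme$version)) {
    out <- c(out, list(issue("STRUCT_SCHEME_MISMATCH", message = sprintf(
      "metadata declares scheme %s_%s but was validated against %s",
      meta$scheme_name, meta$scheme_version, scheme_id(scheme)))))
  }
  declared <- set_names_of(scheme)
  present <- names(meta$tables)
  for (nm in setdiff(declared, present))
    out <- c(out, list(issue("STRUCT_MISSING_SET", nm, message = sprintf(
      "property set '%s' has no table in the metadata", nm))))
  for (nm in setdiff(present, declared))
    out <- c(out, list(issue("STRUCT_UNKNOWN_SET", nm, message = sprintf(
      "table '%s' is not part of scheme %s", nm, scheme_id(scheme)))))
  for (nm in intersect(declared, present)) {
    ps <- get_set(scheme, nm)
    tab <- meta$tables[[nm]]
    for (p in setdiff(prop_names_of(ps), names(tab)))
      out <- c(out, list(issue("STRUCT_MISSING_PROPERTY", nm, p, message = sprintf(
        "property '%s' has no column in table '%s'", p, nm))))
    for (p in setdiff(names(tab), prop_names_of(ps)))
      out <- c(out, list(issue("STRUCT_UNKNOWN_PROPERTY", nm, p, message = sprintf(
        "column '%s' of table '%s' is not declared in the scheme", p, nm))))
    if (ps$cardinality == "exactly-one-row" && nrow(tab) != 1L)
      out <- c(out, list(issue("STRUCT_ROW_COUNT", nm, message = sprintf(
        "set '%s' must have exactly one row but has %d", nm, nrow(tab)))))
  }
  bind_issues(out)
}

# Tables excluded from downstream stages: declared sets that are absent, or
# present with an error-level structural problem. Suppressing them avoids
# cascades (a missing column would otherwise also read as many missing
# values).
excluded_tables <- function(meta, scheme, struct = NULL) {
  struct <- struct %||% validate_structure(meta, scheme)
  bad <- struct$property_set[struct$severity == "error" & nzchar(struct$property_set)]
  unique(c(bad, setdiff(set_names_of(scheme), names(meta$tables))))
}

#' Validate cell values against types, vocabularies and ranges
#'
#' Per declared cell (tables with error-level structural problems are
#' skipped entirely): an empty required cell is an error; a value that does
#' not parse under the declared type is an error; a value outside a closed
#' `allowed` vocabulary is an error while a value outside an open
#' `suggested` vocabulary is only a note; a parsed numeric outside
#' `[minValue, maxValue]` is an error. At most one issue per cell, checked
#' in that order.
#'
#' @inheritParams validate_structure
#' @return Issue data frame.
#' @export
validate_values <- function(meta, scheme) {
  stopifnot(inherits(meta, "md_metadata"), inherits(scheme, "md_scheme"))
  assert_scheme_ok(scheme)
  skip <- excluded_tables(meta, scheme)
  out <- list()
  for (ps in scheme$property_sets) {
    if (ps$name %in% skip) next
    tab <- meta$tables[[ps$name]]
    if (is.null(tab) || nrow(tab) == 0) next
    for (p in ps$properties) {
      if (!p$name %in% names(tab)) next
      vals <- tab[[p$name]]
      for (i in seq_along(vals)) {
        v <- vals[i]
        if (!nzchar(v)) {
          if (p$required)
            out <- c(out, list(issue("VAL_REQUIRED_MISSING", ps$name, p$name, i,
              sprintf("required value '%s' is missing in row %d of '%s'",
                      p$name, i, ps$name))))
          next
        }
        if (!type_ok(v, p$type)) {
          out <- c(out, list(issue("VAL_TYPE", ps$name, p$name, i,
            sprintf("value '%s' does not parse as %s", v, p$type))))
          next
        }
        if (length(p$allowed) > 0 && !v %in% p$allowed) {
          out <- c(out, list(issue("VAL_NOT_ALLOWED", ps$name, p$name, i,
            sprintf("value '%s' is not in the allowed values (%s)",
                    v, paste(p$allowed, collapse = ", ")))))
          next
        }
        if (p$type %in% c("integer", "real")) {
          num <- as.numeric(v)
          lo <- p$min_value %||% -Inf
          hi <- p$max_value %||% Inf
          if (num < lo || num > hi) {
            out <- c(out, list(issue("VAL_RANGE", ps$name, p$name, i,
              sprintf("value %s of '%s' is outside the range [%s, %s]",
                      v, p$name, format(lo), format(hi)))))
            next
          }
        }
        if (length(p$suggested) > 0 && !v %in% p$suggested) {
          out <- c(out, list(issue("VAL_NOT_SUGGESTED", ps$name, p$name, i,
            sprintf("value '%s' is not among the suggested values (%s)",
                    v, paste(p$suggested, collapse = ", ")))))
        }
      }
    }
  }
  bind_issues(out)
}

#' Validate internal consistency of the metadata
#'
#' Three rules, all skipping tables with error-level structural problems:
#' every non-empty value of a `refers_to` property must occur in the
#' referenced column (error); rows of a set sharing the value of its first
#' (key) property are flagged once per duplicated value (warning); and a
#' data file listed in more than one row of the designated data-file set --
#' i.e. assigned more than one measurement and extraction method -- is an
#' error.
#'
#' @inheritParams validate_structure
#' @return Issue data frame.
#' @export
validate_consistency <- function(meta, scheme) {
  stopifnot(inherits(meta, "md_metadata"), inherits(scheme, "md_scheme"))
  assert_scheme_ok(scheme)
  skip <- excluded_tables(meta, scheme)
  out <- list()

  for (ps in scheme$property_sets) {
    if (ps$name %in% skip) next
    tab <- meta$tables[[ps$name]]
    if (is.null(tab)) next

    # Cross-references.
    for (p in ps$properties) {
      if (is.null(p$refers_to) || !p$name %in% names(tab)) next
      target_set <- p$refers_to[1]; target_prop <- p$refers_to[2]
      if (target_set %in% skip) next
      ttab <- meta$tables[[target_set]]
      if (is.null(ttab) || !target_prop %in% names(ttab)) next
      pool <- ttab[[target_prop]]
      vals <- tab[[p$name]]
      for (i in seq_along(vals)) {
        if (nzchar(vals[i]) && !vals[i] %in% pool)
          out <- c(out, list(issue("CONS_DANGLING_REF", ps$name, p$name, i,
            sprintf("value '%s' has no matching '%s' in set '%s'",
                    vals[i], target_prop, target_set))))
      }
    }

    # Duplicate keys (first property of the set).
    key <- prop_names_of(ps)[1]
    if (!is.na(key) && key %in% names(tab) && nrow(tab) > 1) {
      vals <- tab[[key]]
      nz <- which(nzchar(vals))
      for (v in unique(vals[nz][duplicated(vals[nz])])) {
        second <- which(vals == v)[2]
        out <- c(out, list(issue("CONS_DUPLICATE_KEY", ps$name, key, second,
          sprintf("key value '%s' appears in more than one row of '%s'",
                  v, ps$name))))
      }
    }
  }

  # One measurement and extraction method per data file.
  df <- scheme$data_files
  if (!is.null(df) && !df$set %in% skip) {
    tab <- meta$tables[[df$set]]
    if (!is.null(tab) && df$property %in% names(tab)) {
      vals <- tab[[df$property]]
      nz <- which(nzchar(vals))
      for (v in unique(vals[nz][duplicated(vals[nz])])) {
        second <- which(vals == v)[2]
        out <- c(out, list(issue("CONS_MULTIPLE_METHODS", df$set, df$property, second,
          sprintf("data file '%s' is listed in more than one row of '%s' (one measurement and extraction method per data file)",
                  v, df$set))))
      }
    }
  }
  bind_issues(out)
}

read_delim_chr <- function(path, delim) {
  tryCatch(
    utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                      colClasses = "character", check.names = FALSE,
                      na.strings = character(), comment.char = "",
                      stringsAsFactors = FALSE),
    error = function(e) abort_io(sprintf("cannot read data file '%s': %s",
                                         path, conditionMessage(e))))
}

#' Validate metadata against the actual data files
#'
#' Uses the scheme's data-file and data-column designations: every declared
#' file must exist in `data_dir` (missing: error; undeclared files present:
#' warning), every declared column must appear in the file's header
#' (missing: error; undeclared header columns: warning), and every value of
#' a declared column must parse under its declared type (error, one issue
#' per offending column). Skipped entirely when the designated sets have
#' structural errors.
#'
#' @inheritParams validate_structure
#' @param data_dir Directory holding the described delimited data files.
#' @param delim Field delimiter of the data files (default comma; tab
#'   supported).
#' @param max_rows Cap on the number of data rows type-checked per file
#'   (default all rows; files are desk-scale).
#' @return Issue data frame.
#' @export
validate_data_files <- function(meta, scheme, data_dir, delim = ",",
                                max_rows = Inf) {
  stopifnot(inherits(meta, "md_metadata"), inherits(scheme, "md_scheme"))
  assert_scheme_ok(scheme)
  if (!dir.exists(data_dir))
    abort_io(sprintf("data directory '%s' does not exist", data_dir))
  df <- scheme$data_files; dc <- scheme$data_columns
  if (is.null(df) || is.null(dc))
    return(no_issues())
  skip <- excluded_tables(meta, scheme)
  if (df$set %in% skip || dc$set %in% skip) return(no_issues())
  ftab <- meta$tables[[df$set]]
  ctab <- meta$tables[[dc$set]]
  if (is.null(ftab) || !df$property %in% names(ftab)) return(no_issues())
  have_cols <- !is.null(ctab) &&
    all(c(dc$file_property, dc$column_property, dc$type_property) %in% names(ctab))

  out <- list()
  declared <- unique(ftab[[df$property]][nzchar(ftab[[df$property]])])
  on_disk <- sort(list.files(data_dir))

  for (f in setdiff(on_disk, declared))
    out <- c(out, list(issue("DATA_FILE_UNDECLARED", df$set, message = sprintf(
      "file '%s' in '%s' is not declared in '%s'", f, data_dir, df$set))))

  for (f in declared) {
    frow <- which(ftab[[df$property]] == f)[1]
    path <- file.path(data_dir, f)
    if (!file.exists(path)) {
      out <- c(out, list(issue("DATA_FILE_MISSING", df$set, df$property, frow,
        sprintf("declared data file '%s' is missing from '%s'", f, data_dir))))
      next
    }
    content <- read_delim_chr(path, delim)
    header <- names(content)
    if (have_cols) {
      decl_rows <- which(ctab[[dc$file_property]] == f)
      decl_cols <- ctab[[dc$column_property]][decl_rows]
      decl_types <- ctab[[dc$type_property]][decl_rows]
      for (k in seq_along(decl_rows)) {
        col <- decl_cols[k]
        if (!nzchar(col)) next
        if (!col %in% header) {
          out <- c(out, list(issue("DATA_COLUMN_MISSING", dc$set,
            dc$column_property, decl_rows[k],
            sprintf("declared column '%s' is missing from the header of '%s'", col, f))))
          next
        }
        type <- decl_types[k]
        if (!type %in% mds_types) next  # bad declared type is a values-stage finding
        vals <- content[[col]]
        if (is.finite(max_rows)) vals <- utils::head(vals, max_rows)
        ok <- type_ok(vals, type)
        if (!all(ok)) {
          first <- which(!ok)[1]
          out <- c(out, list(issue("DATA_COLUMN_TYPE", dc$set,
            dc$type_property, decl_rows[k],
            sprintf("column '%s' of '%s' declared %s has non-conforming value '%s' (data row %d)",
                    col, f, type, vals[first], first))))
        }
      }
      for (col in setdiff(header, decl_cols))
        out <- c(out, list(issue("DATA_COLUMN_UNDECLARED", dc$set, message = sprintf(
          "header column '%s' of '%s' is not declared in '%s'", col, f, dc$set))))
    }
  }
  bind_issues(out)
}

#' Run all validation stages and assemble a report
#'
#' Runs structure, values, consistency and (when `data_dir` is given and the
#' scheme designates data-file sets) data-file validation, in that order,
#' and assembles the issues into a report whose `worst` field is the maximum
#' severity present, or `"success"` when there is none.
#'
#' @inheritParams validate_data_files
#' @param data_dir Optional directory with the described data files; when
#'   `NULL` the data stage is skipped.
#' @return An object of class `md_validation_report`: list with
#'   `scheme_id`, `timestamp`, `issues` (issue data frame with a `stage`
#'   column) and `worst`.
#' @export
validate_all <- function(meta, scheme, data_dir = NULL, delim = ",",
                         max_rows = Inf) {
  struct <- validate_structure(meta, scheme)
  stages <- list(
    structure = struct,
    values = validate_values(meta, scheme),
    consistency = validate_consistency(meta, scheme)
  )
  if (!is.null(data_dir))
    stages$data <- validate_data_files(meta, scheme, data_dir, delim, max_rows)
  issues <- bind_issues(unname(Map(function(nm, df) {
    if (nrow(df) == 0) return(NULL)
    cbind(stage = nm, df, stringsAsFactors = FALSE)
  }, names(stages), stages)))
  structure(list(
    scheme_id = c(name = scheme$name, version = scheme$version),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    issues = issues,
    worst = worst_severity(issues)
  ), class = "md_validation_report")
}

#' Worst severity of a set of issues
#'
#' @param issues Issue data frame (possibly zero rows).
#' @return `"error"`, `"warning"`, `"note"`, or `"success"` when empty.
#' @export
worst_severity <- function(issues) {
  if (inherits(issues, "md_validation_report")) issues <- issues$issues
  if (is.null(issues) || nrow(issues) == 0) return("success")
  names(severity_rank)[max(severity_rank[issues$severity])]
}

severity_counts <- function(issues) {
  c(error = sum(issues$severity == "error"),
    warning = sum(issues$severity == "warning"),
    note = sum(issues$severity == "note"))
}

#' @export
print.md_validation_report <- function(x, ...) {
  n <- severity_counts(x$issues)
  cat(sprintf("<md_validation_report> %s_%s: %s (%d errors / %d warnings / %d notes)\n",
              x$scheme_id[["name"]], x$scheme_id[["version"]],
              toupper(x$worst), n[["error"]], n[["warning"]], n[["note"]]))
  invisible(x)
}

issue_line <- function(row) {
  loc <- row$property_set
  if (nzchar(row$property)) loc <- paste0(loc, "/", row$property)
  if (row$row > 0) loc <- paste0(loc, ", row ", row$row)
  if (!nzchar(loc)) loc <- "scheme"
  sprintf("[%s] %s (%s): %s", toupper(row$severity), row$code, loc, row$message)
}

#' Render a validation report
#'
#' Produces a human-readable document: a summary header with the per-severity
#' counts and the overall outcome, then every issue listed under its stage
#' and property set with severity badge, rule code, location and message.
#' Rendering is deterministic given the report.
#'
#' @param report An `md_validation_report` from [validate_all()].
#' @param format `"markdown"` or `"html"`.
#' @return The document as a single string.
#' @export
render_report <- function(report, format = c("markdown", "html")) {
  stopifnot(inherits(report, "md_validation_report"))
  if (!is_string(format[1]) || !format[1] %in% c("markdown", "html"))
    abort_usage(sprintf("unsupported report format '%s' (use markdown or html)",
                        as.character(format[1])))
  format <- format[1]
  n <- severity_counts(report$issues)
  summary_line <- sprintf("%d errors / %d warnings / %d notes",
                          n[["error"]], n[["warning"]], n[["note"]])
  title <- sprintf("Validation report: %s_%s",
                   report$scheme_id[["name"]], report$scheme_id[["version"]])

  sections <- character()
  iss <- report$issues
  if (nrow(iss) > 0) {
    for (st in unique(iss$stage)) {
      si <- iss[iss$stage == st, , drop = FALSE]
      sec_lines <- character()
      for (set in unique(si$property_set)) {
        block <- si[si$property_set == set, , drop = FALSE]
        head_nm <- if (nzchar(set)) set else "(scheme)"
        items <- vapply(seq_len(nrow(block)),
                        function(i) issue_line(block[i, , drop = FALSE]), "")
        sec_lines <- c(sec_lines, list(list(name = head_nm, items = items)))
      }
      sections <- c(sections, list(list(stage = st, sets = sec_lines)))
    }
  }

  if (format == "markdown") {
    out <- c(paste0("# ", title), "",
             paste0("- Validated: ", report$timestamp),
             paste0("- Result: **", toupper(report$worst), "**"),
             paste0("- Summary: ", summary_line), "")
    for (sec in sections) {
      out <- c(out, paste0("## Stage: ", sec$stage), "")
      for (s in sec$sets) {
        out <- c(out, paste0("### ", s$name), "",
                 paste0("- ", s$items), "")
      }
    }
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }

  esc <- xml_escape
  out <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
           sprintf("<title>%s</title></head><body>", esc(title)),
           sprintf("<h1>%s</h1>", esc(title)),
           sprintf("<p>Validated: %s</p>", esc(report$timestamp)),
           sprintf("<p>Result: <strong>%s</strong></p>", esc(toupper(report$worst))),
           sprintf("<p class=\"summary\">%s</p>", esc(summary_line)))
  for (sec in sections) {
    out <- c(out, sprintf("<h2>Stage: %s</h2>", esc(sec$stage)))
    for (s in sec$sets) {
      out <- c(out, sprintf("<h3>%s</h3>", esc(s$name)), "<ul>",
               sprintf("<li>%s</li>", esc(s$items)), "</ul>")
    }
  }
  out <- c(out, "</body></html>")
  paste0(paste(out, collapse = "\n"), "\n")
}
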