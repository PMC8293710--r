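# XML export: combined documents and one document per data file.
#
# Export is gated on validation: it refuses whenever an error-level issue
# exists and succeeds with warnings or notes only. Element names are the
# scheme's property-set and property names (whitespace-free by scheme
# invariant); each table row becomes one <record>; missing values are
# absent elements.

xml_ns_uri <- function(scheme) sprintf("urn:mdscheme:%s:%s", scheme$name, scheme$version)

export_gate <- function(meta, scheme) {
  report <- validate_all(meta, scheme)
  n_err <- sum(report$issues$severity == "error")
  if (n_err > 0)
    abort_export(sprintf(
      "export refused: validation found %d error(s); fix them and re-validate", n_err))
  invisible(report)
}

# Serialize one metadata table subset into a property-set element.
add_set_element <- function(root, ps, tab, rows = seq_len(nrow(tab))) {
  set_node <- xml2::xml_add_child(root, ps$name)
  pnames <- prop_names_of(ps)
  for (i in rows) {
    rec <- xml2::xml_add_child(set_node, "record")
    for (p in pnames) {
      if (!p %in% names(tab)) next
      v <- tab[[p]][i]
      if (nzchar(v)) xml2::xml_add_child(rec, p, v)
    }
  }
  set_node
}

build_xml <- function(meta, scheme, row_filter = NULL, data_file = NULL) {
  root_args <- list(.value = scheme$name,
                    schemeVersion = scheme$version,
                    xmlns = xml_ns_uri(scheme))
  if (!is.null(data_file)) root_args$dataFile <- data_file
  doc <- do.call(xml2::xml_new_root, root_args)
  for (ps in scheme$property_sets) {
    tab <- meta$tables[[ps$name]]
    if (is.null(tab)) tab <- empty_metadata(scheme)$tables[[ps$name]]
    rows <- seq_len(nrow(tab))
    if (!is.null(row_filter)) rows <- rows[row_filter(ps$name, tab)]
    add_set_element(doc, ps, tab, rows)
  }
  doc
}

#' Export metadata to a single XML document
#'
#' Serializes the whole metadata set in scheme order. Refused with an error
#' when validation finds error-level issues; warnings and notes do not
#' block export.
#'
#' @param meta An [md_metadata()].
#' @param scheme The declaring [md_scheme()].
#' @param path Optional output file; when given the document is also
#'   written there.
#' @param validate Gate the export on error-free validation (default). Turn
#'   off only to preview the serialization of template-shaped (still empty,
#'   hence incomplete) metadata.
#' @return An `xml_document`, invisibly when `path` is given.
#' @export
export_xml <- function(meta, scheme, path = NULL, validate = TRUE) {
  stopifnot(inherits(meta, "md_metadata"), inherits(scheme, "md_scheme"))
  assert_scheme_ok(scheme)
  if (isTRUE(validate)) export_gate(meta, scheme)
  doc <- build_xml(meta, scheme)
  if (!is.null(path)) {
    xml2::write_xml(doc, path, options = c("format", "no_declaration"))
    return(invisible(doc))
  }
  doc
}

# Which data files is each row of each multi-row set associated with?
# Data-file rows are seeded with their own file; associations then propagate
# along refers_to links (in both directions) to a fixed point, except that
# data-file rows never relay associations between other rows -- otherwise two
# files sharing one measurement would leak into each other's documents.
# Rows with an empty association set belong to every per-file document.
row_filesets <- function(meta, scheme) {
  df <- scheme$data_files
  stopifnot(!is.null(df))
  sets <- set_names_of(scheme)
  filesets <- lapply(sets, function(nm) {
    tab <- meta$tables[[nm]]
    n <- if (is.null(tab)) 0L else nrow(tab)
    rep(list(character(0)), n)
  })
  names(filesets) <- sets

  ftab <- meta$tables[[df$set]]
  if (!is.null(ftab) && df$property %in% names(ftab)) {
    for (i in seq_len(nrow(ftab))) {
      f <- ftab[[df$property]][i]
      if (nzchar(f)) filesets[[df$set]][[i]] <- f
    }
  }

  # refers_to edges: (source set, source property) -> (target set, target prop)
  edges <- list()
  for (ps in scheme$property_sets) {
    for (p in ps$properties) {
      if (!is.null(p$refers_to))
        edges <- c(edges, list(list(s_set = ps$name, s_prop = p$name,
                                    t_set = p$refers_to[1], t_prop = p$refers_to[2])))
    }
  }

  repeat {
    changed <- FALSE
    for (e in edges) {
      stab <- meta$tables[[e$s_set]]; ttab <- meta$tables[[e$t_set]]
      if (is.null(stab) || is.null(ttab)) next
      if (!e$s_prop %in% names(stab) || !e$t_prop %in% names(ttab)) next
      for (i in seq_len(nrow(stab))) {
        v <- stab[[e$s_prop]][i]
        if (!nzchar(v)) next
        targets <- which(ttab[[e$t_prop]] == v)
        for (j in targets) {
          # target -> source
          if (e$s_set != df$set) {
            new <- union(filesets[[e$s_set]][[i]], filesets[[e$t_set]][[j]])
            if (length(new) > length(filesets[[e$s_set]][[i]])) {
              filesets[[e$s_set]][[i]] <- new; changed <- TRUE
            }
          }
          # source -> target
          if (e$t_set != df$set) {
            new <- union(filesets[[e$t_set]][[j]], filesets[[e$s_set]][[i]])
            if (length(new) > length(filesets[[e$t_set]][[j]])) {
              filesets[[e$t_set]][[j]] <- new; changed <- TRUE
            }
          }
        }
      }
    }
    if (!changed) break
  }
  filesets
}

#' Export metadata to one XML document per data file
#'
#' For every row of the designated data-file set, writes
#' `<dataFileName>.xml` containing the full experiment-level
#' (exactly-one-row) sets -- replicated verbatim into each document so that
#' each file's metadata is self-contained -- and only those rows of
#' multi-row sets that are associated with this data file through
#' `refers_to` chains. Rows associated with no data file are conservatively
#' included in every document.
#'
#' @inheritParams export_xml
#' @param out_dir Output directory (created if absent).
#' @return Named list (file name -> `xml_document`), invisibly.
#' @export
export_xml_per_datafile <- function(meta, scheme, out_dir) {
  stopifnot(inherits(meta, "md_metadata"), inherits(scheme, "md_scheme"))
  assert_scheme_ok(scheme)
  if (is.null(scheme$data_files))
    abort_definition("scheme does not designate a data-file property set")
  export_gate(meta, scheme)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  df <- scheme$data_files
  ftab <- meta$tables[[df$set]]
  files <- if (is.null(ftab) || !df$property %in% names(ftab)) character(0) else
    ftab[[df$property]][nzchar(ftab[[df$property]])]
  if (length(files) == 0) return(invisible(stats::setNames(list(), character(0))))
  if (anyDuplicated(basename(paste0(files, ".xml"))))
    abort_io("per-data-file export would produce colliding output names")

  filesets <- row_filesets(meta, scheme)
  one_row_sets <- set_names_of(scheme)[vapply(scheme$property_sets, function(ps)
    ps$cardinality == "exactly-one-row", logical(1))]

  docs <- list()
  for (f in files) {
    row_filter <- function(set_name, tab) {
      if (set_name %in% one_row_sets) return(rep(TRUE, nrow(tab)))
      if (set_name == df$set) return(tab[[df$property]] == f)
      fs <- filesets[[set_name]]
      vapply(seq_len(nrow(tab)), function(i)
        length(fs[[i]]) == 0 || f %in% fs[[i]], logical(1))
    }
    doc <- build_xml(meta, scheme, row_filter = row_filter, data_file = f)
    out_path <- file.path(out_dir, paste0(basename(f), ".xml"))
    xml2::write_xml(doc, out_path, options = c("format", "no_declaration"))
    docs[[f]] <- doc
  }
  invisible(docs)
}

#' Read exported XML back into a metadata set
#'
#' Inverse of [export_xml()] up to the missing-value representation (absent
#' elements read back as empty strings). Supplying the scheme aligns column
#' sets and order exactly, including columns that happen to be entirely
#' empty; without it, columns are reconstructed in order of first
#' appearance.
#'
#' @param x Path to an XML file, an XML string, or an `xml_document`.
#' @param scheme Optional [md_scheme()] the document was exported from.
#' @return An [md_metadata()].
#' @export
read_metadata_xml <- function(x, scheme = NULL) {
  # xml2 documents are mutable pointers; re-parse so that stripping the
  # namespace never alters the caller's document
  if (inherits(x, "xml_document")) x <- as.character(x)
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) abort_format(
                    sprintf("not a well-formed XML document: %s", conditionMessage(e))))
  xml2::xml_ns_strip(doc)
  version <- xml2::xml_attr(doc, "schemeVersion")
  name <- xml2::xml_name(doc)
  if (is.na(version))
    abort_format("XML root carries no schemeVersion attribute: not exported metadata")
  if (!is.null(scheme) && !identical(name, scheme$name))
    abort_format(sprintf("XML root '%s' does not match scheme '%s'", name, scheme$name))

  tables <- list()
  for (set_node in xml2::xml_children(doc)) {
    set_name <- xml2::xml_name(set_node)
    records <- xml2::xml_children(set_node)
    cols <- character(0)
    if (!is.null(scheme)) {
      ps <- get_set(scheme, set_name)
      if (!is.null(ps)) cols <- prop_names_of(ps)
    }
    rows <- lapply(records, function(rec) {
      kids <- xml2::xml_children(rec)
      stats::setNames(xml2::xml_text(kids), xml2::xml_name(kids))
    })
    if (is.null(scheme))
      for (r in rows) cols <- union(cols, names(r))
    tab <- if (length(cols) == 0) {
      data.frame()
    } else {
      out <- lapply(cols, function(cn)
        vapply(rows, function(r) if (cn %in% names(r)) r[[cn]] else "", ""))
      names(out) <- cols
      do.call(data.frame, c(out, list(stringsAsFactors = FALSE, check.names = FALSE)))
    }
    tables[[set_name]] <- tab
  }
  md_metadata(name, version, tables)
}

#' Report coverage of a mapping onto a general metadata standard
#'
#' The hook for translating a domain scheme into a broad standard such as
#' the Ecological Metadata Language: given a mapping from property paths
#' (`"Set/Property"`) to target paths, reports which scheme properties are
#' mapped, which are not, and which mapping entries dangle (name no
#' existing property). No target-standard emission is performed.
#'
#' @param scheme An [md_scheme()].
#' @param mapping Named character vector: `names()` are property paths,
#'   values are target (e.g. EML) paths.
#' @return Data frame with columns `property_path`, `target_path`,
#'   `mapped`; dangling mapping entries in `attr(, "dangling")`.
#' @export
eml_mapping_stub <- function(scheme, mapping = character()) {
  stopifnot(inherits(scheme, "md_scheme"))
  paths <- unlist(lapply(scheme$property_sets, function(ps)
    paste(ps$name, prop_names_of(ps), sep = "/")))
  target <- unname(mapping[match(paths, names(mapping))])
  out <- data.frame(property_path = paths,
                    target_path = ifelse(is.na(target), "", target),
                    mapped = !is.na(target), stringsAsFactors = FALSE)
  attr(out, "dangling") <- setdiff(names(mapping), paths)
  out
}
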