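# Scheme model: the in-memory definition of a domain-specific metadata scheme.

#' Define a metadata property
#'
#' A property is one metadata field within a property set: a typed value slot
#' with an optional controlled vocabulary, numeric range, and cross-reference
#' to a property in another set.
#'
#' Vocabularies are mutually exclusive: `allowed` is a closed list (any other
#' value is a validation error) and `suggested` is an open list (other values
#' only produce a note), so a property declares at most one of the two.
#'
#' @param name Identifier, unique within its property set, no whitespace.
#' @param type One of `"character"`, `"integer"`, `"real"`, `"logical"`,
#'   `"date"` (ISO-8601, `YYYY-MM-DD`).
#' @param description Free-text description shown in the entry workbook.
#' @param required Must every row carry a non-empty value?
#' @param allowed,suggested Character vectors of vocabulary values.
#' @param min_value,max_value Optional inclusive numeric bounds; only
#'   meaningful for `integer`/`real` properties.
#' @param refers_to Optional length-2 character vector
#'   `c(propertySet, property)`: every non-empty value of this property must
#'   occur in the referenced column.
#' @param example Optional example value.
#' @return An object of class `md_property`.
#' @export
#' @examples
#' md_property("Device", "character",
#'             suggested = c("flowcytometer", "microscope"))
md_property <- function(name, type = "character", description = "",
                        required = FALSE, allowed = character(),
                        suggested = character(), min_value = NULL,
                        max_value = NULL, refers_to = NULL, example = NULL) {
  if (!is_string(name)) abort_definition("property name must be a single string")
  if (!is_string(type)) abort_definition("property type must be a single string")
  p <- list(
    name = name, description = as.character(description)[1] %||% "",
    type = type, required = isTRUE(required),
    allowed = as.character(allowed), suggested = as.character(suggested),
    min_value = if (is.null(min_value)) NULL else as.numeric(min_value)[1],
    max_value = if (is.null(max_value)) NULL else as.numeric(max_value)[1],
    refers_to = if (is.null(refers_to)) NULL else as.character(refers_to),
    example = if (is.null(example)) NULL else as.character(example)[1]
  )
  structure(p, class = "md_property")
}

#' Define a property set
#'
#' A property set is a named group of related properties, rendered as one
#' worksheet of the entry workbook. `cardinality` distinguishes
#' experiment-level sheets holding exactly one record
#' (`"exactly-one-row"`) from per-record sheets (`"zero-or-more-rows"`).
#'
#' @param name Identifier, unique within the scheme, no whitespace.
#' @param properties List of [md_property()] objects (order is preserved
#'   everywhere: workbook columns, XML elements, manifests).
#' @param description Free-text description.
#' @param cardinality `"zero-or-more-rows"` or `"exactly-one-row"`.
#' @return An object of class `md_property_set`.
#' @export
md_property_set <- function(name, properties = list(), description = "",
                            cardinality = c("zero-or-more-rows", "exactly-one-row")) {
  if (!is_string(name)) abort_definition("property set name must be a single string")
  cardinality <- match.arg(cardinality)
  if (!all(vapply(properties, inherits, logical(1), "md_property")))
    abort_definition("properties must be md_property objects")
  structure(list(
    name = name, description = as.character(description)[1] %||% "",
    cardinality = cardinality, properties = properties
  ), class = "md_property_set")
}

#' Define a metadata scheme
#'
#' A scheme is a named, versioned, ordered collection of property sets,
#' optionally designating which set lists the described data files and which
#' set describes their columns (used by data-file validation and per-file
#' export).
#'
#' @param name Identifier, no whitespace.
#' @param version Semantic version string (`MAJOR.MINOR.PATCH`).
#' @param property_sets List of [md_property_set()] objects.
#' @param description Free-text description.
#' @param data_files Optional designation
#'   `list(set = <set name>, property = <file-name property>)`.
#' @param data_columns Optional designation `list(set =, file_property =,
#'   column_property =, type_property =)` naming the set whose rows declare
#'   one data-file column each.
#' @return An object of class `md_scheme`.
#' @export
md_scheme <- function(name, version, property_sets = list(), description = "",
                      data_files = NULL, data_columns = NULL) {
  if (!is_string(name) || !nzchar(name))
    abort_definition("scheme name must be a non-empty string")
  if (is.null(parse_semver(version)))
    abort_definition(sprintf("'%s' is not a semantic version", as.character(version)[1]))
  if (!all(vapply(property_sets, inherits, logical(1), "md_property_set")))
    abort_definition("property_sets must be md_property_set objects")
  structure(list(
    name = name, version = version,
    description = as.character(description)[1] %||% "",
    property_sets = property_sets,
    data_files = data_files, data_columns = data_columns
  ), class = "md_scheme")
}

#' @export
print.md_scheme <- function(x, ...) {
  cat(sprintf("<md_scheme> %s\n", scheme_id(x)))
  for (ps in x$property_sets) {
    cat(sprintf("  %s [%s]: %s\n", ps$name, ps$cardinality,
                paste(vapply(ps$properties, `[[`, "", "name"), collapse = ", ")))
  }
  invisible(x)
}

#' Scheme identifier string
#'
#' @param scheme An [md_scheme()].
#' @return `"<name>_<version>"`, the unique identifier of a scheme release.
#' @export
scheme_id <- function(scheme) paste0(scheme$name, "_", scheme$version)

set_names_of <- function(scheme) vapply(scheme$property_sets, `[[`, "", "name")
prop_names_of <- function(ps) vapply(ps$properties, `[[`, "", "name")

get_set <- function(scheme, name) {
  i <- match(name, set_names_of(scheme))
  if (is.na(i)) NULL else scheme$property_sets[[i]]
}

get_prop <- function(ps, name) {
  i <- match(name, prop_names_of(ps))
  if (is.na(i)) NULL else ps$properties[[i]]
}

#' Create the minimal template scheme
#'
#' The starting point from which domain schemes are grown: a single
#' exactly-one-row property set `"Metadata"` with required `Title`, `Author`
#' and `Date` properties. Domain schemes are built by adding property sets
#' and properties to this template (or from scratch with [md_scheme()]).
#'
#' @param name Scheme name (default `"dmdScheme"`).
#' @param version Semantic version string.
#' @return An [md_scheme()] that passes [check_scheme_definition()].
#' @export
#' @examples
#' s <- new_template_scheme("dmdScheme", "0.9.9")
#' check_scheme_definition(s)
new_template_scheme <- function(name = "dmdScheme", version = "0.9.9") {
  md_scheme(
    name = name, version = version,
    description = "Template metadata scheme: grow a domain-specific scheme from it.",
    property_sets = list(
      md_property_set(
        "Metadata", cardinality = "exactly-one-row",
        description = "Core identification of the described dataset.",
        properties = list(
          md_property("Title", "character", "Title of the dataset.", required = TRUE),
          md_property("Author", "character", "Person responsible for the data.", required = TRUE),
          md_property("Date", "date", "Date of data creation (YYYY-MM-DD).", required = TRUE)
        )
      )
    )
  )
}

#' Check that a scheme definition is well-formed
#'
#' Verifies the structural invariants of a scheme: non-empty whitespace-free
#' unique names, a recognised type per property, at most one vocabulary per
#' property with every vocabulary value parsing under the declared type,
#' ranges only on numeric properties with `min <= max`, and cross-references
#' resolving to an existing property. Problems are returned, not raised.
#'
#' @param scheme An [md_scheme()].
#' @return A data frame with columns `property_set`, `property`, `rule`,
#'   `message`; zero rows iff the scheme is well-formed.
#' @export
check_scheme_definition <- function(scheme) {
  stopifnot(inherits(scheme, "md_scheme"))
  problems <- list()
  bad <- function(set, prop, rule, message) {
    problems[[length(problems) + 1L]] <<-
      data.frame(property_set = set, property = prop, rule = rule,
                 message = message, stringsAsFactors = FALSE)
  }

  if (!nzchar(scheme$name) || grepl("\\s", scheme$name))
    bad("", "", "scheme-name", "scheme name must be non-empty without whitespace")
  if (is.null(parse_semver(scheme$version)))
    bad("", "", "scheme-version", sprintf("'%s' is not a semantic version", scheme$version))

  snames <- set_names_of(scheme)
  if (anyDuplicated(snames))
    for (d in unique(snames[duplicated(snames)]))
      bad(d, "", "duplicate-set-name", sprintf("property set '%s' defined more than once", d))

  for (ps in scheme$property_sets) {
    if (!nzchar(ps$name) || grepl("\\s", ps$name))
      bad(ps$name, "", "set-name", "property set name must be non-empty without whitespace")
    if (length(ps$properties) == 0L)
      bad(ps$name, "", "no-properties", sprintf("property set '%s' has no properties", ps$name))
    pnames <- prop_names_of(ps)
    if (anyDuplicated(pnames))
      for (d in unique(pnames[duplicated(pnames)]))
        bad(ps$name, d, "duplicate-property-name",
            sprintf("property '%s' defined more than once in '%s'", d, ps$name))

    for (p in ps$properties) {
      loc <- function(rule, msg) bad(ps$name, p$name, rule, msg)
      if (!nzchar(p$name) || grepl("\\s", p$name))
        loc("property-name", "property name must be non-empty without whitespace")
      if (!p$type %in% mds_types)
        loc("property-type", sprintf("unknown type '%s'", p$type))
      if (length(p$allowed) > 0 && length(p$suggested) > 0)
        loc("both-vocabularies",
            "allowedValues and suggestedValues cannot both be non-empty")
      if (p$type %in% mds_types) {
        for (v in c(p$allowed, p$suggested)) {
          if (!all(type_ok(v, p$type)))
            loc("vocabulary-type",
                sprintf("vocabulary value '%s' does not parse as %s", v, p$type))
        }
      }
      has_range <- !is.null(p$min_value) || !is.null(p$max_value)
      if (has_range && !p$type %in% c("integer", "real"))
        loc("range-type", "numeric range declared on a non-numeric property")
      if (!is.null(p$min_value) && !is.null(p$max_value) && p$min_value > p$max_value)
        loc("range-order", "minValue exceeds maxValue")
      if (!is.null(p$refers_to)) {
        rt <- p$refers_to
        if (length(rt) != 2L) {
          loc("refers-to", "refersTo must name a (propertySet, property) pair")
        } else {
          target <- get_set(scheme, rt[1])
          if (is.null(target)) {
            loc("dangling-refers-to",
                sprintf("refersTo names missing property set '%s'", rt[1]))
          } else if (is.null(get_prop(target, rt[2]))) {
            loc("dangling-refers-to",
                sprintf("refersTo names missing property '%s' in set '%s'", rt[2], rt[1]))
          }
        }
      }
    }
  }

  # Designations must resolve too.
  chk_desig <- function(d, what, props) {
    if (is.null(d)) return()
    tgt <- get_set(scheme, d$set %||% "")
    if (is.null(tgt)) {
      bad(d$set %||% "", "", "designation",
          sprintf("%s designation names missing property set", what))
      return()
    }
    for (f in props)
      if (is.null(get_prop(tgt, d[[f]] %||% "")))
        bad(d$set, d[[f]] %||% "", "designation",
            sprintf("%s designation names missing property", what))
  }
  chk_desig(scheme$data_files, "data-file", "property")
  chk_desig(scheme$data_columns, "data-column",
            c("file_property", "column_property", "type_property"))

  if (length(problems) == 0L)
    return(data.frame(property_set = character(), property = character(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, problems)
}

assert_scheme_ok <- function(scheme) {
  probs <- check_scheme_definition(scheme)
  if (nrow(probs) > 0)
    abort_definition(sprintf(
      "scheme definition has %d problem(s); first: %s", nrow(probs), probs$message[1]))
  invisible(scheme)
}

#' Add a property set to a scheme
#'
#' Mutating operations have value semantics: the input scheme is unchanged
#' and an extended copy is returned, which keeps iterative scheme
#' development reproducible.
#'
#' @param scheme An [md_scheme()].
#' @param ps An [md_property_set()] whose name is not yet used.
#' @return The extended scheme.
#' @export
add_property_set <- function(scheme, ps) {
  stopifnot(inherits(scheme, "md_scheme"), inherits(ps, "md_property_set"))
  if (ps$name %in% set_names_of(scheme))
    abort_definition(sprintf("property set '%s' already exists", ps$name))
  scheme$property_sets <- c(scheme$property_sets, list(ps))
  scheme
}

#' Remove a property set from a scheme
#'
#' Inverse of [add_property_set()]; mainly used while iterating on a scheme
#' under development.
#'
#' @inheritParams add_property_set
#' @param name Name of the property set to drop.
#' @return The reduced scheme.
#' @export
remove_property_set <- function(scheme, name) {
  stopifnot(inherits(scheme, "md_scheme"))
  i <- match(name, set_names_of(scheme))
  if (is.na(i)) abort_definition(sprintf("no property set '%s'", name))
  scheme$property_sets <- scheme$property_sets[-i]
  scheme
}

#' Add a property to an existing property set
#'
#' @inheritParams add_property_set
#' @param set_name Name of the property set to extend.
#' @param p An [md_property()] whose name is not yet used in that set.
#' @return The extended scheme.
#' @export
add_property <- function(scheme, set_name, p) {
  stopifnot(inherits(scheme, "md_scheme"), inherits(p, "md_property"))
  i <- match(set_name, set_names_of(scheme))
  if (is.na(i)) abort_definition(sprintf("no property set '%s'", set_name))
  ps <- scheme$property_sets[[i]]
  if (p$name %in% prop_names_of(ps))
    abort_definition(sprintf("property '%s' already exists in '%s'", p$name, set_name))
  ps$properties <- c(ps$properties, list(p))
  scheme$property_sets[[i]] <- ps
  scheme
}

# ---- JSON manifest --------------------------------------------------------
# One JSON document per scheme; field names follow the scheme vocabulary
# (propertySets, allowedValues, ...). This is the machine-readable form
# shipped inside scheme packages.

property_to_list <- function(p) {
  out <- list(name = p$name, description = p$description, type = p$type,
              required = p$required, allowedValues = I(p$allowed),
              suggestedValues = I(p$suggested))
  if (!is.null(p$min_value)) out$minValue <- p$min_value
  if (!is.null(p$max_value)) out$maxValue <- p$max_value
  if (!is.null(p$refers_to))
    out$refersTo <- list(propertySet = p$refers_to[1], property = p$refers_to[2])
  if (!is.null(p$example)) out$example <- p$example
  out
}

scheme_to_list <- function(scheme) {
  out <- list(
    name = scheme$name, version = scheme$version,
    description = scheme$description,
    propertySets = lapply(scheme$property_sets, function(ps) list(
      name = ps$name, description = ps$description,
      cardinality = ps$cardinality,
      properties = lapply(ps$properties, property_to_list)
    ))
  )
  if (!is.null(scheme$data_files))
    out$dataFiles <- list(propertySet = scheme$data_files$set,
                          property = scheme$data_files$property)
  if (!is.null(scheme$data_columns))
    out$dataColumns <- list(propertySet = scheme$data_columns$set,
                            fileProperty = scheme$data_columns$file_property,
                            columnProperty = scheme$data_columns$column_property,
                            typeProperty = scheme$data_columns$type_property)
  out
}

#' Write a scheme manifest (JSON)
#'
#' @param scheme An [md_scheme()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "md_scheme"))
  json <- jsonlite::toJSON(scheme_to_list(scheme), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a scheme manifest (JSON)
#'
#' @param path Path to a manifest written by [write_scheme_json()].
#' @return An [md_scheme()].
#' @export
read_scheme_json <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cannot read scheme manifest '%s'", path))
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) abort_format(
                  sprintf("'%s' is not a valid scheme manifest: %s", path, conditionMessage(e))))
  if (!is.list(x) || is.null(x$name) || is.null(x$version) || is.null(x$propertySets))
    abort_format(sprintf("'%s' is not a valid scheme manifest", path))
  sets <- lapply(x$propertySets, function(ps) {
    md_property_set(
      name = ps$name, description = ps$description %||% "",
      cardinality = ps$cardinality %||% "zero-or-more-rows",
      properties = lapply(ps$properties, function(p) md_property(
        name = p$name, type = p$type %||% "character",
        description = p$description %||% "", required = isTRUE(p$required),
        allowed = unlist(p$allowedValues) %||% character(),
        suggested = unlist(p$suggestedValues) %||% character(),
        min_value = p$minValue, max_value = p$maxValue,
        refers_to = if (!is.null(p$refersTo))
          c(p$refersTo$propertySet, p$refersTo$property),
        example = p$example
      ))
    )
  })
  md_scheme(
    name = x$name, version = x$version, description = x$description %||% "",
    property_sets = sets,
    data_files = if (!is.null(x$dataFiles))
      list(set = x$dataFiles$propertySet, property = x$dataFiles$property),
    data_columns = if (!is.null(x$dataColumns))
      list(set = x$dataColumns$propertySet,
           file_property = x$dataColumns$fileProperty,
           column_property = x$dataColumns$columnProperty,
           type_property = x$dataColumns$typeProperty)
  )
}
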