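# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed conditions so callers (and the CLI) can map failures to outcomes.
mds_abort <- function(message, class) {
  stop(structure(
    class = c(class, "mds_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

abort_definition <- function(msg) mds_abort(msg, "mds_definition_error")
abort_format     <- function(msg) mds_abort(msg, "mds_format_error")
abort_io         <- function(msg) mds_abort(msg, "mds_io_error")
abort_usage      <- function(msg) mds_abort(msg, "mds_usage_error")
abort_repository <- function(msg) mds_abort(msg, "mds_repository_error")
abort_integrity  <- function(msg) mds_abort(msg, "mds_integrity_error")
abort_generator  <- function(msg) mds_abort(msg, "mds_generator_error")
abort_export     <- function(msg) mds_abort(msg, "mds_export_error")

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Semantic versions: MAJOR.MINOR.PATCH with an optional pre-release tag.
parse_semver <- function(x) {
  if (!is_string(x)) return(NULL)
  m <- regmatches(x, regexec("^([0-9]+)\\.([0-9]+)\\.([0-9]+)(?:-([0-9A-Za-z.-]+))?$", x))[[1]]
  if (length(m) == 0L) return(NULL)
  list(
    major = as.integer(m[2]), minor = as.integer(m[3]), patch = as.integer(m[4]),
    prerelease = if (nzchar(m[5])) m[5] else NA_character_
  )
}

# Numeric fieldwise comparison; pre-release sorts below its release.
semver_compare <- function(a, b) {
  pa <- parse_semver(a); pb <- parse_semver(b)
  if (is.null(pa) || is.null(pb)) abort_definition("not a semantic version")
  for (f in c("major", "minor", "patch")) {
    if (pa[[f]] != pb[[f]]) return(as.integer(sign(pa[[f]] - pb[[f]])))
  }
  if (is.na(pa$prerelease) && !is.na(pb$prerelease)) return(1L)
  if (!is.na(pa$prerelease) && is.na(pb$prerelease)) return(-1L)
  if (identical(pa$prerelease, pb$prerelease)) return(0L)
  if (pa$prerelease > pb$prerelease) 1L else -1L
}

# Run code under a given RNG seed, restoring the caller's RNG state after.
run_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# The value type system: character, integer, real, logical, date (ISO-8601).
mds_types <- c("character", "integer", "real", "logical", "date")

# Does each string parse under the declared type? Empty strings are "missing"
# and always acceptable here; required-ness is a separate rule.
type_ok <- function(values, type) {
  v <- as.character(values)
  ok <- rep(TRUE, length(v))
  nz <- nzchar(v)
  if (!any(nz)) return(ok)
  x <- v[nz]
  ok[nz] <- switch(type,
    character = rep(TRUE, length(x)),
    integer   = grepl("^[+-]?[0-9]+$", x),
    real      = grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x),
    logical   = toupper(x) %in% c("TRUE", "FALSE"),
    date      = grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", x) &
                !is.na(suppressWarnings(as.Date(x, format = "%Y-%m-%d"))),
    abort_definition(sprintf("unknown type '%s'", type))
  )
  ok
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Absolute-path coercion (zip and friends resolve relative paths elsewhere).
abs_path <- function(path) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(getwd(), path)
}

# Fixed timestamp stamped onto archive members so identical content yields
# byte-identical zip files.
mds_epoch <- function() as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

stamp_tree <- function(root, files) {
  for (f in files) Sys.setFileTime(file.path(root, f), mds_epoch())
  dirs <- unique(c(root, file.path(root, unique(dirname(files)))))
  dirs <- dirs[dir.exists(dirs)]
  for (d in dirs) Sys.setFileTime(d, mds_epoch())
  invisible(NULL)
}

zip_deterministic <- function(zipfile, files, root) {
  stamp_tree(root, files)
  zip::zip(abs_path(zipfile), files = files, root = root, mode = "mirror",
           compression_level = 6, include_directories = FALSE)
  invisible(zipfile)
}
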