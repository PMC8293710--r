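# Versioned scheme repository: packing schemes into checksummed zip
# archives and listing/installing them from a local directory or a static
# URL carrying an index.json. No server-side logic; offline-first.

manifest_name <- "manifest.json"

sha256_file <- function(path) digest::digest(file = path, algo = "sha256")

# Checksum over the member contents (sorted "name:sha256" lines), so that
# unpack -> repack yields the same manifest even though it is a new archive.
content_checksum <- function(root, files) {
  lines <- sort(vapply(files, function(f)
    paste0(f, ":", sha256_file(file.path(root, f))), ""))
  digest::digest(paste(lines, collapse = "\n"), algo = "sha256", serialize = FALSE)
}

#' Pack a scheme into a distributable archive
#'
#' Bundles the scheme manifest (JSON), the empty template workbook, and the
#' example filled workbook(s) into `<name>_<version>.zip` together with a
#' package manifest carrying a checksum of the member contents. Examples
#' must validate against the scheme without errors; otherwise packaging is
#' refused.
#'
#' @param scheme An [md_scheme()] passing [check_scheme_definition()].
#' @param examples Named list of [md_metadata()] example fillings (may be
#'   empty).
#' @param out_dir Directory to write the archive into (created if absent).
#' @return An object of class `md_scheme_package`: list with `name`,
#'   `version`, `path`, `manifest`.
#' @export
pack_scheme <- function(scheme, examples = list(), out_dir = ".") {
  stopifnot(inherits(scheme, "md_scheme"))
  assert_scheme_ok(scheme)
  if (length(examples) > 0 && is.null(names(examples)))
    names(examples) <- sprintf("example-%d", seq_along(examples))
  for (nm in names(examples)) {
    rep <- validate_all(examples[[nm]], scheme)
    n_err <- sum(rep$issues$severity == "error")
    if (n_err > 0)
      abort_definition(sprintf(
        "packaging refused: example '%s' has %d validation error(s)", nm, n_err))
  }

  stage <- tempfile("mds_pack_")
  dir.create(file.path(stage, "examples"), recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE))
  write_scheme_json(scheme, file.path(stage, "scheme.json"))
  write_template_workbook(scheme, file.path(stage, "template.xlsx"))
  files <- c("scheme.json", "template.xlsx")
  for (nm in names(examples)) {
    rel <- file.path("examples", paste0(nm, ".xlsx"))
    write_filled_workbook(scheme, examples[[nm]], file.path(stage, rel))
    files <- c(files, rel)
  }
  manifest <- list(
    name = scheme$name, version = scheme$version,
    description = scheme$description,
    files = as.list(stats::setNames(
      vapply(files, function(f) sha256_file(file.path(stage, f)), ""), files)),
    contentChecksum = content_checksum(stage, files)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(stage, manifest_name), useBytes = TRUE)
  files <- c(files, manifest_name)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  archive <- file.path(out_dir, paste0(scheme_id(scheme), ".zip"))
  zip_deterministic(archive, files, stage)
  structure(list(name = scheme$name, version = scheme$version,
                 path = archive, manifest = manifest),
            class = "md_scheme_package")
}

#' @export
print.md_scheme_package <- function(x, ...) {
  cat(sprintf("<md_scheme_package> %s_%s at %s\n", x$name, x$version, x$path))
  invisible(x)
}

read_package_manifest <- function(archive) {
  tmp <- tempfile("mds_manifest_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  zip::unzip(archive, files = manifest_name, exdir = tmp)
  jsonlite::fromJSON(file.path(tmp, manifest_name), simplifyVector = TRUE)
}

is_url <- function(x) grepl("^https?://", x)

#' Build (or rebuild) a repository index
#'
#' Scans a directory for scheme archives and writes `index.json` listing
#' `(name, version, path, checksum)` per archive, where `checksum` is the
#' SHA-256 of the archive file itself (verified on install).
#'
#' @param repo_dir Directory holding `<name>_<version>.zip` archives.
#' @return The index as a data frame, invisibly.
#' @export
build_repo_index <- function(repo_dir) {
  if (!dir.exists(repo_dir)) abort_io(sprintf("'%s' is not a directory", repo_dir))
  archives <- sort(list.files(repo_dir, pattern = "\\.zip$"))
  entries <- lapply(archives, function(a) {
    m <- read_package_manifest(file.path(repo_dir, a))
    list(name = m$name, version = m$version, path = a,
         checksum = sha256_file(file.path(repo_dir, a)))
  })
  writeLines(jsonlite::toJSON(entries, auto_unbox = TRUE, pretty = TRUE),
             file.path(repo_dir, "index.json"), useBytes = TRUE)
  invisible(index_to_df(entries))
}

index_to_df <- function(entries) {
  if (length(entries) == 0)
    return(data.frame(name = character(), version = character(),
                      path = character(), checksum = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(entries, function(e)
    data.frame(name = e$name %||% NA_character_,
               version = e$version %||% NA_character_,
               path = e$path %||% NA_character_,
               checksum = e$checksum %||% NA_character_,
               stringsAsFactors = FALSE)))
  if (anyNA(df) || any(!nzchar(as.matrix(df))))
    abort_repository("repository index has incomplete entries")
  if (anyDuplicated(paste(df$name, df$version)))
    abort_repository("repository index lists duplicate (name, version) pairs")
  # name ascending, then version descending by semver
  ord <- order(df$name)
  df <- df[ord, , drop = FALSE]
  out <- lapply(split(seq_len(nrow(df)), df$name), function(ix) {
    vs <- df$version[ix]
    parsed <- lapply(vs, function(v) {
      p <- parse_semver(v)
      if (is.null(p)) abort_repository(sprintf("invalid version '%s' in index", v))
      p
    })
    cmp <- order(vapply(parsed, `[[`, 0L, "major"),
                 vapply(parsed, `[[`, 0L, "minor"),
                 vapply(parsed, `[[`, 0L, "patch"), decreasing = TRUE)
    df[ix[cmp], , drop = FALSE]
  })
  out <- do.call(rbind, out[sort(names(out))])
  rownames(out) <- NULL
  out
}

#' List the schemes available in a repository
#'
#' @param repo_uri Local directory or `http(s)` URL containing
#'   `index.json`.
#' @return Data frame of entries, sorted by name then descending semantic
#'   version.
#' @export
list_schemes <- function(repo_uri) {
  index_path <- if (is_url(repo_uri)) paste0(sub("/$", "", repo_uri), "/index.json")
                else file.path(repo_uri, "index.json")
  if (!is_url(repo_uri) && !file.exists(index_path))
    abort_repository(sprintf("no index.json found at '%s'", repo_uri))
  entries <- tryCatch(jsonlite::fromJSON(index_path, simplifyVector = FALSE),
                      error = function(e) abort_repository(
                        sprintf("cannot parse repository index at '%s': %s",
                                repo_uri, conditionMessage(e))))
  if (!is.list(entries)) abort_repository("repository index is not a JSON array")
  index_to_df(entries)
}

resolve_version <- function(entries, name, version) {
  mine <- entries[entries$name == name, , drop = FALSE]
  if (nrow(mine) == 0)
    abort_repository(sprintf("no scheme '%s' in the repository", name))
  if (identical(version, "latest")) {
    stable <- mine$version[vapply(mine$version, function(v)
      is.na(parse_semver(v)$prerelease), logical(1))]
    if (length(stable) == 0)
      abort_repository(sprintf("scheme '%s' has only pre-release versions", name))
    best <- stable[1]
    for (v in stable) if (semver_compare(v, best) > 0) best <- v
    version <- best
  }
  row <- mine[mine$version == version, , drop = FALSE]
  if (nrow(row) == 0)
    abort_repository(sprintf("no version '%s' of scheme '%s' in the repository",
                             version, name))
  row
}

#' Install a scheme from a repository
#'
#' Fetches the archive for `(name, version)` -- `"latest"` resolves by
#' semantic-version ordering, pre-release tags excluded -- verifies its
#' SHA-256 against the index, and unpacks it into `dest_dir` (default: a
#' per-session temporary directory, so installation never touches the
#' repository or the user's library). The repository itself is never
#' modified.
#'
#' @inheritParams list_schemes
#' @param name Scheme name.
#' @param version Version string, or `"latest"`.
#' @param dest_dir Optional directory to unpack into.
#' @return List with the loaded `scheme`, the install `dir`, and the
#'   unpacked `files`.
#' @export
install_scheme <- function(repo_uri, name, version = "latest", dest_dir = NULL) {
  entries <- list_schemes(repo_uri)
  row <- resolve_version(entries, name, version)

  local_archive <- tempfile("mds_archive_", fileext = ".zip")
  on.exit(unlink(local_archive))
  if (is_url(repo_uri)) {
    src <- paste0(sub("/$", "", repo_uri), "/", row$path)
    status <- tryCatch(utils::download.file(src, local_archive, quiet = TRUE, mode = "wb"),
                       error = function(e) -1L)
    if (!identical(status, 0L))
      abort_repository(sprintf("cannot download archive '%s'", src))
  } else {
    src <- file.path(repo_uri, row$path)
    if (!file.exists(src))
      abort_repository(sprintf("archive '%s' is missing from the repository", row$path))
    file.copy(src, local_archive, overwrite = TRUE)
  }
  if (!identical(sha256_file(local_archive), row$checksum))
    abort_integrity(sprintf(
      "checksum mismatch for '%s': the archive does not match the repository index",
      row$path))

  if (is.null(dest_dir))
    dest_dir <- file.path(tempdir(), "mdscheme_schemes",
                          paste0(row$name, "_", row$version))
  if (!dir.exists(dest_dir)) dir.create(dest_dir, recursive = TRUE)
  zip::unzip(local_archive, exdir = dest_dir)
  scheme <- read_scheme_json(file.path(dest_dir, "scheme.json"))
  list(scheme = scheme, dir = dest_dir,
       files = sort(list.files(dest_dir, recursive = TRUE)))
}
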