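# Synthetic-data generator.
#
# Builds the example Experimental-Microbial-Ecology scheme, clean filled
# metadata, toy delimited data files, and a throwaway repository -- plus
# deterministic fault injection: a fault specification maps rule codes to
# counts, and the generator records the exact (code, severity, location)
# triples a validator must report. This makes every validation rule
# testable with an oracle that is independent of the validator itself.
#
# The vocabularies (protist species, measurement devices, culture media)
# are invented but domain-plausible; value ranges and row counts are chosen
# to look like a small microcosm experiment.

eme_species <- c("Tetrahymena thermophila", "Colpidium striatum",
                 "Didinium nasutum", "Euplotes daidaleos",
                 "Loxocephalus sp.", "Spirostomum teres")
eme_trophic <- c("bacterivore", "predator", "omnivore", "autotroph")
eme_media <- c("protist pellet medium", "wheat seed medium", "spring water")
eme_devices <- c("flowcytometer", "microscope", "videocamera", "spectrophotometer")
eme_software <- c("bemovi", "flowcore", "imagej")

#' Build the example Experimental Microbial Ecology scheme
#'
#' A deterministic, fully featured scheme exercising every capability of
#' the model: an exactly-one-row `Experiment` set; multi-row `Species`,
#' `Treatment`, `Measurement`, `DataExtraction`, `DataFiles` and
#' `DataFileColumns` sets; closed and open vocabularies; numeric ranges;
#' and cross-references `Treatment -> Species`,
#' `DataFiles -> Measurement/DataExtraction`,
#' `DataFileColumns -> DataFiles`. `DataFiles`/`DataFileColumns` are
#' designated as the data-file and data-column sets.
#'
#' @param version Scheme version (default `"0.9.9"`).
#' @return An [md_scheme()] named `"emeScheme"` passing
#'   [check_scheme_definition()].
#' @export
make_example_scheme <- function(version = "0.9.9") {
  md_scheme(
    name = "emeScheme", version = version,
    description = "Example metadata scheme for Experimental Microbial Ecology microcosm data.",
    data_files = list(set = "DataFiles", property = "FileName"),
    data_columns = list(set = "DataFileColumns", file_property = "FileName",
                        column_property = "ColumnName", type_property = "ColumnType"),
    property_sets = list(
      md_property_set("Experiment", cardinality = "exactly-one-row",
        description = "Experiment-level metadata, entered once.",
        properties = list(
          md_property("Name", "character", "Short experiment name.", required = TRUE),
          md_property("Description", "character", "What was done and why."),
          md_property("StartDate", "date", "First day of the experiment.", required = TRUE),
          md_property("Temperature_C", "real", "Incubation temperature.",
                      min_value = 0, max_value = 40),
          md_property("Duration_days", "integer", "Length of the experiment.",
                      min_value = 1, max_value = 365),
          md_property("ContactEmail", "character", "Responsible researcher.")
        )),
      md_property_set("Species",
        description = "Organisms used in the experiment.",
        properties = list(
          md_property("SpeciesName", "character", "Binomial name.", required = TRUE,
                      allowed = eme_species),
          md_property("CommonLabel", "character", "Label used in data files.",
                      required = TRUE),
          md_property("BodySize_um", "real", "Typical cell length.",
                      min_value = 0, max_value = 10000),
          md_property("GrowthRate_per_day", "real", "Intrinsic growth rate."),
          md_property("TrophicGroup", "character", "Feeding mode.",
                      allowed = eme_trophic),
          md_property("CultureMedium", "character", "Stock culture medium.",
                      suggested = eme_media)
        )),
      md_property_set("Treatment",
        description = "Experimental treatments applied to the microcosms.",
        properties = list(
          md_property("TreatmentID", "character", "Treatment identifier.", required = TRUE),
          md_property("SpeciesName", "character", "Species this treatment applies to.",
                      refers_to = c("Species", "SpeciesName")),
          md_property("Temperature_C", "real", "Treatment temperature.",
                      min_value = 0, max_value = 40),
          md_property("Replicates", "integer", "Number of replicate microcosms.",
                      min_value = 1, max_value = 100)
        )),
      md_property_set("Measurement",
        description = "Measurement methods producing raw data.",
        properties = list(
          md_property("MeasurementID", "character", "Measurement identifier.", required = TRUE),
          md_property("Device", "character", "Measuring device.",
                      suggested = eme_devices),
          md_property("SamplingVolume_ml", "real", "Sampled volume.",
                      min_value = 0, max_value = 50)
        )),
      md_property_set("DataExtraction",
        description = "Processing steps turning raw data into analysis-ready data.",
        properties = list(
          md_property("ExtractionID", "character", "Extraction identifier.", required = TRUE),
          md_property("Software", "character", "Extraction software.",
                      suggested = eme_software),
          md_property("SoftwareVersion", "character", "Software version used.")
        )),
      md_property_set("DataFiles",
        description = "One row per data file; assigns each file its measurement and extraction method.",
        properties = list(
          md_property("FileID", "character", "File identifier.", required = TRUE),
          md_property("FileName", "character", "Name of the file in the data directory.",
                      required = TRUE),
          md_property("MeasurementID", "character", "Measurement that produced the file.",
                      refers_to = c("Measurement", "MeasurementID")),
          md_property("ExtractionID", "character", "Extraction that produced the file.",
                      refers_to = c("DataExtraction", "ExtractionID")),
          md_property("Description", "character", "Content of the file.")
        )),
      md_property_set("DataFileColumns",
        description = "One row per column of each data file.",
        properties = list(
          md_property("ColumnID", "character", "Unique column identifier.", required = TRUE),
          md_property("FileName", "character", "File this column belongs to.",
                      refers_to = c("DataFiles", "FileName")),
          md_property("ColumnName", "character", "Header name in the file.", required = TRUE),
          md_property("ColumnType", "character", "Value type of the column.",
                      allowed = mds_types),
          md_property("Description", "character", "Meaning of the column.")
        ))
    )
  )
}

toy_columns <- data.frame(
  name = c("sample_id", "day", "abundance"),
  type = c("character", "integer", "real"),
  stringsAsFactors = FALSE
)

make_clean_tables <- function(n_species, n_datafiles) {
  if (n_species < 1 || n_species > length(eme_species))
    abort_generator(sprintf("n_species must be between 1 and %d", length(eme_species)))
  if (n_datafiles < 0)
    abort_generator("n_datafiles must be non-negative")
  sp <- eme_species[seq_len(n_species)]
  tables <- list(
    Experiment = data.frame(
      Name = "microcosm-warming",
      Description = "Protist microcosms along a temperature gradient.",
      StartDate = "2021-03-01",
      Temperature_C = "20",
      Duration_days = "42",
      ContactEmail = "lab@example.org",
      stringsAsFactors = FALSE, check.names = FALSE),
    Species = data.frame(
      SpeciesName = sp,
      CommonLabel = sprintf("sp%02d", seq_len(n_species)),
      BodySize_um = sprintf("%.1f", round(stats::runif(n_species, 20, 400), 1)),
      GrowthRate_per_day = sprintf("%.2f", round(stats::runif(n_species, 0.1, 2), 2)),
      TrophicGroup = eme_trophic[(seq_len(n_species) - 1L) %% length(eme_trophic) + 1L],
      CultureMedium = eme_media[(seq_len(n_species) - 1L) %% length(eme_media) + 1L],
      stringsAsFactors = FALSE, check.names = FALSE),
    Treatment = data.frame(
      TreatmentID = sprintf("T%02d", seq_len(n_species)),
      SpeciesName = sp,
      Temperature_C = sprintf("%d", 15 + 5 * ((seq_len(n_species) - 1L) %% 3L)),
      Replicates = "3",
      stringsAsFactors = FALSE, check.names = FALSE),
    Measurement = data.frame(
      MeasurementID = sprintf("M%02d", seq_len(max(n_datafiles, 1L))),
      Device = eme_devices[(seq_len(max(n_datafiles, 1L)) - 1L) %% length(eme_devices) + 1L],
      SamplingVolume_ml = "0.5",
      stringsAsFactors = FALSE, check.names = FALSE),
    DataExtraction = data.frame(
      ExtractionID = c("E01", "E02"),
      Software = eme_software[c(1, 2)],
      SoftwareVersion = c("1.0.3", "2.1.0"),
      stringsAsFactors = FALSE, check.names = FALSE)
  )
  file_names <- sprintf("counts_%02d.csv", seq_len(n_datafiles))
  tables$DataFiles <- data.frame(
    FileID = sprintf("F%02d", seq_len(n_datafiles)),
    FileName = file_names,
    MeasurementID = sprintf("M%02d", seq_len(n_datafiles)),
    ExtractionID = c("E01", "E02")[(seq_len(n_datafiles) - 1L) %% 2L + 1L],
    Description = sprintf("Species counts from measurement M%02d.", seq_len(n_datafiles)),
    stringsAsFactors = FALSE, check.names = FALSE)[seq_len(n_datafiles), , drop = FALSE]
  tables$DataFileColumns <- do.call(rbind, c(list(
    data.frame(ColumnID = character(), FileName = character(),
               ColumnName = character(), ColumnType = character(),
               Description = character(), stringsAsFactors = FALSE)),
    lapply(seq_len(n_datafiles), function(i) data.frame(
      ColumnID = paste0("F", sprintf("%02d", i), ".", toy_columns$name),
      FileName = file_names[i],
      ColumnName = toy_columns$name,
      ColumnType = toy_columns$type,
      Description = c("Sample identifier.", "Day of the experiment.",
                      "Individuals per ml."),
      stringsAsFactors = FALSE))))
  rownames(tables$DataFileColumns) <- NULL
  tables
}

expected_row <- function(code, set = "", property = "", row = 0L) {
  data.frame(code = code, severity = rule_severity(code),
             property_set = set, property = property, row = as.integer(row),
             stringsAsFactors = FALSE)
}

no_expected <- function() {
  data.frame(code = character(), severity = character(),
             property_set = character(), property = character(),
             row = integer(), stringsAsFactors = FALSE)
}

check_fault_spec <- function(faults) {
  if (is.null(faults) || length(faults) == 0) return(stats::setNames(integer(), character()))
  if (is.null(names(faults)) || any(!nzchar(names(faults))))
    abort_generator("fault spec must be a named vector of rule-code counts")
  bad <- setdiff(names(faults), rule_table()$code)
  if (length(bad) > 0)
    abort_generator(sprintf("unknown rule code(s) in fault spec: %s",
                            paste(bad, collapse = ", ")))
  counts <- as.integer(faults)
  if (any(is.na(counts) | counts < 0))
    abort_generator("fault counts must be non-negative integers")
  stats::setNames(counts, names(faults))
}

pick_sites <- function(sites, k, code) {
  if (k > nrow(sites))
    abort_generator(sprintf(
      "cannot seed %d '%s' fault(s): only %d seedable site(s)", k, code, nrow(sites)))
  if (k == 0) return(sites[0, , drop = FALSE])
  sites[sort(sample(nrow(sites), k)), , drop = FALSE]
}

cell_site_pool <- function(tables, spec) {
  # spec: list of c(set, property) pairs eligible for one rule code
  do.call(rbind, lapply(spec, function(sp) {
    tab <- tables[[sp[1]]]
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    data.frame(set = sp[1], property = sp[2], row = seq_len(nrow(tab)),
               stringsAsFactors = FALSE)
  })) %||% data.frame(set = character(), property = character(), row = integer())
}

# Bad replacement value for a seeded cell fault.
bad_value_for <- function(code, set, property) {
  switch(code,
    VAL_TYPE = if (property == "Replicates") "3.7" else "not-a-number",
    VAL_NOT_ALLOWED = "parasitoid",
    VAL_NOT_SUGGESTED = if (property == "Device") "flowcytometer2" else "tap water",
    VAL_RANGE = if (property == "BodySize_um") "99999" else "99",
    CONS_DANGLING_REF = if (property == "SpeciesName") "Paramecium caudatum" else "E99",
    abort_generator(sprintf("no bad value defined for '%s'", code)))
}

# Site pools per cell-level rule code; disjoint by construction so that
# independently seeded faults never collide on a cell.
cell_pools <- function(tables) {
  list(
    VAL_REQUIRED_MISSING = cell_site_pool(tables, list(
      c("Species", "CommonLabel"), c("DataFileColumns", "ColumnID"))),
    VAL_TYPE = cell_site_pool(tables, list(
      c("Species", "GrowthRate_per_day"), c("Treatment", "Replicates"))),
    VAL_NOT_ALLOWED = cell_site_pool(tables, list(
      c("Species", "TrophicGroup"))),
    VAL_NOT_SUGGESTED = cell_site_pool(tables, list(
      c("Species", "CultureMedium"), c("Measurement", "Device"))),
    VAL_RANGE = cell_site_pool(tables, list(
      c("Species", "BodySize_um"), c("Treatment", "Temperature_C"))),
    CONS_DANGLING_REF = cell_site_pool(tables, list(
      c("Treatment", "SpeciesName"), c("DataFiles", "ExtractionID")))
  )
}

struct_fault_order <- c("STRUCT_UNKNOWN_PROPERTY", "STRUCT_UNKNOWN_SET",
                        "STRUCT_ROW_COUNT", "STRUCT_MISSING_PROPERTY",
                        "STRUCT_MISSING_SET", "STRUCT_SCHEME_MISMATCH")
data_fault_codes <- c("DATA_FILE_MISSING", "DATA_FILE_UNDECLARED",
                      "DATA_COLUMN_MISSING", "DATA_COLUMN_UNDECLARED",
                      "DATA_COLUMN_TYPE")

#' Generate filled example metadata, optionally with seeded faults
#'
#' Produces metadata over the example scheme that validates with zero
#' issues when `faults` is empty. With a fault specification (named vector
#' mapping rule codes to counts), the requested number of independent
#' violations of each rule is injected at randomly chosen (seeded) sites,
#' and the exact issues a validator must report are returned alongside.
#' Site pools for different rules are disjoint, and structural faults are
#' only applied to tables untouched by other faults, so seeded expectations
#' are exact: `validate_all()` restricted to the seeded codes reports
#' precisely these issues. Requesting more faults than there are seedable
#' sites raises a generator error.
#'
#' Faults with `DATA_*` codes describe how [make_toy_datafiles()] will
#' corrupt the written data files; they are recorded in the expectations
#' here and realized there (pass the same `faults` and `seed`).
#'
#' @param scheme The [make_example_scheme()] scheme (any version).
#' @param n_species Number of species/treatment rows (1 to 6).
#' @param n_datafiles Number of declared data files.
#' @param faults Named integer vector, e.g. `c(VAL_NOT_ALLOWED = 2)`.
#' @param seed Integer seed; identical inputs give identical output.
#' @return List with `meta` (an [md_metadata()]) and `expected` (data frame
#'   of seeded issues: `code`, `severity`, `property_set`, `property`,
#'   `row`).
#' @export
make_filled_metadata <- function(scheme = make_example_scheme(), n_species = 3,
                                 n_datafiles = 3, faults = NULL, seed = 1) {
  stopifnot(inherits(scheme, "md_scheme"))
  needed <- c("Experiment", "Species", "Treatment", "Measurement",
              "DataExtraction", "DataFiles", "DataFileColumns")
  if (!identical(set_names_of(scheme), needed))
    abort_generator("make_filled_metadata requires the example scheme shape")
  faults <- check_fault_spec(faults)

  run_seeded(seed, {
    tables <- make_clean_tables(n_species, n_datafiles)
    expected <- list()
    touched <- character(0)   # tables carrying a seeded fault expectation
    protected <- character(0) # tables that must stay structurally intact
    if (any(names(faults) %in% data_fault_codes))
      protected <- c("DataFiles", "DataFileColumns")

    # -- cell-level faults --------------------------------------------------
    claimed_rows <- character(0)  # "set|row" keys carrying a seeded bad cell
    pools <- cell_pools(tables)
    for (code in names(pools)) {
      k <- faults[code]
      if (is.na(k) || k == 0) next
      sites <- pick_sites(pools[[code]], k, code)
      for (i in seq_len(nrow(sites))) {
        s <- sites[i, ]
        claimed_rows <- union(claimed_rows, paste(s$set, s$row, sep = "|"))
        newv <- if (code == "VAL_REQUIRED_MISSING") "" else
          bad_value_for(code, s$set, s$property)
        tables[[s$set]][s$row, s$property] <- newv
        expected <- c(expected, list(expected_row(code, s$set, s$property, s$row)))
        touched <- union(touched, s$set)
        if (code == "CONS_DANGLING_REF") {
          # the referenced table must keep its rows for the oracle to hold
          ref_target <- if (s$property == "SpeciesName") "Species" else "DataExtraction"
          touched <- union(touched, ref_target)
        }
      }
    }

    # -- row-level faults ---------------------------------------------------
    k <- faults["CONS_DUPLICATE_KEY"]
    if (!is.na(k) && k > 0) {
      pool <- rbind(
        data.frame(set = "Species", row = seq_len(nrow(tables$Species))),
        data.frame(set = "DataExtraction", row = seq_len(nrow(tables$DataExtraction))))
      # duplicating a row that carries a seeded bad cell would duplicate
      # that fault too, so only pristine rows are eligible
      pool <- pool[!paste(pool$set, pool$row, sep = "|") %in% claimed_rows, , drop = FALSE]
      sites <- pick_sites(pool, k, "CONS_DUPLICATE_KEY")
      for (i in seq_len(nrow(sites))) {
        s <- sites[i, ]
        tab <- tables[[s$set]]
        tables[[s$set]] <- rbind(tab, tab[s$row, , drop = FALSE])
        rownames(tables[[s$set]]) <- NULL
        key <- names(tab)[1]
        expected <- c(expected, list(expected_row(
          "CONS_DUPLICATE_KEY", s$set, key, nrow(tables[[s$set]]))))
        touched <- union(touched, s$set)
      }
    }

    k <- faults["CONS_MULTIPLE_METHODS"]
    if (!is.na(k) && k > 0) {
      pool <- data.frame(row = seq_len(nrow(tables$DataFiles)))
      pool <- pool[!paste("DataFiles", pool$row, sep = "|") %in% claimed_rows, , drop = FALSE]
      sites <- pick_sites(pool, k, "CONS_MULTIPLE_METHODS")
      meas <- tables$Measurement$MeasurementID
      for (i in seq_len(nrow(sites))) {
        orig <- tables$DataFiles[sites$row[i], , drop = FALSE]
        extra <- orig
        extra$FileID <- paste0(orig$FileID, "x")
        extra$MeasurementID <- meas[meas != orig$MeasurementID][1] %||% orig$MeasurementID
        tables$DataFiles <- rbind(tables$DataFiles, extra)
        rownames(tables$DataFiles) <- NULL
        expected <- c(expected, list(expected_row(
          "CONS_MULTIPLE_METHODS", "DataFiles", "FileName",
          nrow(tables$DataFiles))))
        touched <- union(touched, "DataFiles")
      }
    }

    # -- data-file faults (realized by make_toy_datafiles) ------------------
    if (any(names(faults) %in% data_fault_codes)) {
      plan <- plan_data_faults(tables, faults, seed)
      expected <- c(expected, list(plan$expected))
    }

    # -- structural faults --------------------------------------------------
    version_shift <- 0L
    for (code in struct_fault_order) {
      k <- faults[code]
      if (is.na(k) || k == 0) next
      if (code == "STRUCT_UNKNOWN_PROPERTY") {
        eligible <- names(tables)
        for (i in seq_len(k)) {
          set <- eligible[(i - 1L) %% length(eligible) + 1L]
          col <- sprintf("ExtraCol%d", i)
          tables[[set]][[col]] <- rep("", nrow(tables[[set]]))
          expected <- c(expected, list(expected_row(code, set, col)))
        }
      } else if (code == "STRUCT_UNKNOWN_SET") {
        for (i in seq_len(k)) {
          nm <- sprintf("ExtraSheet%d", i)
          tables[[nm]] <- data.frame(Note = "unexpected", stringsAsFactors = FALSE)
          expected <- c(expected, list(expected_row(code, nm)))
        }
      } else if (code == "STRUCT_ROW_COUNT") {
        if (k > 1 || "Experiment" %in% touched)
          abort_generator("cannot seed more than one STRUCT_ROW_COUNT fault (one exactly-one-row set)")
        tables$Experiment <- rbind(tables$Experiment, tables$Experiment)
        rownames(tables$Experiment) <- NULL
        expected <- c(expected, list(expected_row(code, "Experiment")))
        touched <- union(touched, "Experiment")
      } else if (code == "STRUCT_MISSING_PROPERTY") {
        eligible <- setdiff(names(tables), c(touched, protected))
        eligible <- eligible[!grepl("^ExtraSheet", eligible)]
        sites <- pick_sites(data.frame(set = eligible, stringsAsFactors = FALSE),
                            k, code)
        for (set in sites$set) {
          ps <- get_set(scheme, set)
          col <- prop_names_of(ps)[length(ps$properties)]
          tables[[set]][[col]] <- NULL
          expected <- c(expected, list(expected_row(code, set, col)))
          touched <- union(touched, set)
        }
      } else if (code == "STRUCT_MISSING_SET") {
        eligible <- setdiff(names(tables), c(touched, protected))
        eligible <- eligible[!grepl("^ExtraSheet", eligible)]
        sites <- pick_sites(data.frame(set = eligible, stringsAsFactors = FALSE),
                            k, code)
        for (set in sites$set) {
          tables[[set]] <- NULL
          expected <- c(expected, list(expected_row(code, set)))
          touched <- union(touched, set)
        }
      } else if (code == "STRUCT_SCHEME_MISMATCH") {
        if (k > 1)
          abort_generator("cannot seed more than one STRUCT_SCHEME_MISMATCH fault")
        version_shift <- 1L
        expected <- c(expected, list(expected_row(code)))
      }
    }

    version <- scheme$version
    if (version_shift > 0) {
      p <- parse_semver(version)
      version <- sprintf("%d.%d.%d", p$major, p$minor, p$patch + 1L)
    }
    expected <- bind_expected(expected)
    list(meta = md_metadata(scheme$name, version, tables), expected = expected)
  })
}

bind_expected <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  lst <- lst[vapply(lst, nrow, 0L) > 0]
  if (length(lst) == 0) return(no_expected())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# Joint plan for DATA_* faults over the clean-declared files/columns.
# Deterministic in (tables content, faults, seed); called identically from
# make_filled_metadata (to record expectations) and make_toy_datafiles (to
# realize them).
plan_data_faults <- function(tables, faults, seed) {
  ftab <- tables$DataFiles
  ctab <- tables$DataFileColumns
  if (is.null(ftab) || is.null(ctab))
    abort_generator("metadata does not declare data files")
  files <- unique(ftab$FileName[nzchar(ftab$FileName)])
  run_seeded(seed + 7919L, {
    expected <- list()
    plan <- list(skip_files = character(), drop_cols = NULL, type_cols = NULL,
                 extra_cols = NULL, extra_files = character())
    claimed_cols <- character(0)  # "file|column" already used by one fault

    k <- faults["DATA_FILE_MISSING"]
    if (!is.na(k) && k > 0) {
      sites <- pick_sites(data.frame(file = files, stringsAsFactors = FALSE),
                          k, "DATA_FILE_MISSING")
      plan$skip_files <- sites$file
      for (f in sites$file)
        expected <- c(expected, list(expected_row(
          "DATA_FILE_MISSING", "DataFiles", "FileName",
          which(ftab$FileName == f)[1])))
    }
    writable <- setdiff(files, plan$skip_files)

    col_pool <- function(types = mds_types) {
      ix <- which(ctab$FileName %in% writable & ctab$ColumnType %in% types &
                  !paste(ctab$FileName, ctab$ColumnName, sep = "|") %in% claimed_cols)
      data.frame(decl_row = ix, file = ctab$FileName[ix],
                 column = ctab$ColumnName[ix], type = ctab$ColumnType[ix],
                 stringsAsFactors = FALSE)
    }

    k <- faults["DATA_COLUMN_MISSING"]
    if (!is.na(k) && k > 0) {
      sites <- pick_sites(col_pool(), k, "DATA_COLUMN_MISSING")
      plan$drop_cols <- sites
      claimed_cols <- c(claimed_cols, paste(sites$file, sites$column, sep = "|"))
      for (i in seq_len(nrow(sites)))
        expected <- c(expected, list(expected_row(
          "DATA_COLUMN_MISSING", "DataFileColumns", "ColumnName",
          sites$decl_row[i])))
    }

    k <- faults["DATA_COLUMN_TYPE"]
    if (!is.na(k) && k > 0) {
      sites <- pick_sites(col_pool(setdiff(mds_types, "character")),
                          k, "DATA_COLUMN_TYPE")
      plan$type_cols <- sites
      claimed_cols <- c(claimed_cols, paste(sites$file, sites$column, sep = "|"))
      for (i in seq_len(nrow(sites)))
        expected <- c(expected, list(expected_row(
          "DATA_COLUMN_TYPE", "DataFileColumns", "ColumnType",
          sites$decl_row[i])))
    }

    k <- faults["DATA_COLUMN_UNDECLARED"]
    if (!is.na(k) && k > 0) {
      if (length(writable) == 0)
        abort_generator("cannot seed DATA_COLUMN_UNDECLARED: no writable data files")
      plan$extra_cols <- data.frame(
        file = writable[(seq_len(k) - 1L) %% length(writable) + 1L],
        column = sprintf("extra%d", seq_len(k)), stringsAsFactors = FALSE)
      for (i in seq_len(k))
        expected <- c(expected, list(expected_row(
          "DATA_COLUMN_UNDECLARED", "DataFileColumns")))
    }

    k <- faults["DATA_FILE_UNDECLARED"]
    if (!is.na(k) && k > 0) {
      plan$extra_files <- sprintf("undeclared_%02d.csv", seq_len(k))
      for (i in seq_len(k))
        expected <- c(expected, list(expected_row(
          "DATA_FILE_UNDECLARED", "DataFiles")))
    }

    list(plan = plan, expected = bind_expected(expected))
  })
}

toy_value <- function(type, colname, i) {
  switch(type,
    character = sprintf("%s_%d", colname, i),
    integer = as.character(i),
    real = sprintf("%.2f", round(stats::runif(1, 0, 100), 2)),
    logical = c("TRUE", "FALSE")[i %% 2L + 1L],
    date = sprintf("2021-03-%02d", i),
    sprintf("%s_%d", colname, i))
}

#' Write toy data files matching (or deliberately violating) the metadata
#'
#' Writes one delimited file per file declared in the metadata's
#' `DataFiles` table, with exactly the declared header columns and five
#' typed data rows, so that [validate_data_files()] is clean by
#' construction. `DATA_*` fault codes corrupt the output as instructed
#' (file not written, declared column dropped, non-conforming value placed,
#' extra column or extra file added); pass the same `faults` and `seed` as
#' to [make_filled_metadata()] so the recorded expectations match.
#'
#' @param meta Metadata from [make_filled_metadata()].
#' @param data_dir Output directory (created if absent).
#' @param faults Named integer vector of `DATA_*` rule-code counts.
#' @param seed Integer seed; identical inputs give byte-identical files.
#' @return List with `files` (paths written) and `expected` (seeded issue
#'   data frame).
#' @export
make_toy_datafiles <- function(meta, data_dir, faults = NULL, seed = 1) {
  stopifnot(inherits(meta, "md_metadata"))
  faults <- check_fault_spec(faults)
  faults <- faults[names(faults) %in% data_fault_codes]
  if (is.null(meta$tables$DataFiles) || is.null(meta$tables$DataFileColumns))
    abort_generator("metadata does not declare data files")
  if (!dir.exists(data_dir)) dir.create(data_dir, recursive = TRUE)

  planned <- plan_data_faults(meta$tables, faults, seed)
  plan <- planned$plan
  ftab <- meta$tables$DataFiles
  ctab <- meta$tables$DataFileColumns
  files <- unique(ftab$FileName[nzchar(ftab$FileName)])

  written <- character(0)
  run_seeded(seed + 104729L, {
    for (f in setdiff(files, plan$skip_files)) {
      cols <- ctab[ctab$FileName == f & nzchar(ctab$ColumnName), , drop = FALSE]
      drop <- plan$drop_cols
      if (!is.null(drop))
        cols <- cols[!(paste(f, cols$ColumnName, sep = "|") %in%
                       paste(drop$file, drop$column, sep = "|")), , drop = FALSE]
      content <- lapply(seq_len(nrow(cols)), function(j)
        vapply(1:5, function(i) toy_value(cols$ColumnType[j], cols$ColumnName[j], i), ""))
      names(content) <- cols$ColumnName
      df <- do.call(data.frame,
                    c(content, list(stringsAsFactors = FALSE, check.names = FALSE)))
      tc <- plan$type_cols
      if (!is.null(tc)) {
        mine <- tc[tc$file == f, , drop = FALSE]
        for (j in seq_len(nrow(mine)))
          df[3, mine$column[j]] <- "oops"
      }
      ec <- plan$extra_cols
      if (!is.null(ec)) {
        mine <- ec[ec$file == f, , drop = FALSE]
        for (j in seq_len(nrow(mine)))
          df[[mine$column[j]]] <- rep("x", nrow(df))
      }
      path <- file.path(data_dir, f)
      utils::write.csv(df, path, row.names = FALSE)
      written <- c(written, path)
    }
    for (f in plan$extra_files) {
      df <- data.frame(stray = c("a", "b"), stringsAsFactors = FALSE)
      path <- file.path(data_dir, f)
      utils::write.csv(df, path, row.names = FALSE)
      written <- c(written, path)
    }
  })
  list(files = written, expected = planned$expected)
}

#' Build a throwaway fixture repository
#'
#' Packs the example scheme twice (versions 0.9.9 and 1.1.7, mirroring a
#' scheme that evolved after publication), each with one clean example
#' filling, into `repo_dir`, and writes the repository index.
#'
#' @param repo_dir Directory for the repository (created if absent).
#' @param seed Integer seed for the example fillings.
#' @return `repo_dir`, invisibly.
#' @export
make_fixture_repository <- function(repo_dir, seed = 1) {
  if (!dir.exists(repo_dir)) dir.create(repo_dir, recursive = TRUE)
  for (v in c("0.9.9", "1.1.7")) {
    scheme <- make_example_scheme(version = v)
    ex <- make_filled_metadata(scheme, seed = seed)
    pack_scheme(scheme, examples = list(filled = ex$meta), out_dir = repo_dir)
  }
  build_repo_index(repo_dir)
  invisible(repo_dir)
}
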