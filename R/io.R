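#' Registry file I/O and schema validation
#'
#' A registry on disk is a directory of seven UTF-8, comma-delimited CSV
#' files with mandatory header rows: `patients.csv`, `encounters.csv`,
#' `injections.csv`, `diagnoses.csv`, `procedures.csv`, `va.csv`,
#' `iop.csv`. All dates are ISO-8601. Unknown extra columns are ignored
#' with a warning; missing required columns, unparseable dates, and drug
#' names outside the anti-VEGF vocabulary are errors naming the offending
#' file and row.
#'
#' @name registry_io
NULL

registry_schema <- function() {
  list(
    patients = c("patient_id", "age_at_first_record", "gender", "race"),
    encounters = c("patient_id", "date", "provider_type"),
    injections = c("patient_id", "laterality", "date", "drug"),
    diagnoses = c("patient_id", "laterality", "date", "code_category"),
    procedures = c("patient_id", "laterality", "date", "category"),
    va = c("patient_id", "laterality", "date", "snellen_num", "snellen_den"),
    iop = c("patient_id", "laterality", "date", "mmHg")
  )
}

parse_date_column <- function(x, file) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & x != "")
  if (length(bad)) {
    stop(sprintf("%s: unparseable date '%s' at row %d", file,
                 x[bad[1]], bad[1]), call. = FALSE)
  }
  d
}

#' Validate a registry object
#'
#' @param registry A list of the seven tables.
#' @param config A [criterion_config()] supplying the drug vocabulary.
#' @return The registry, invisibly; errors name the offending table/row.
#' @export
validate_registry <- function(registry, config = criterion_config()) {
  schema <- registry_schema()
  for (tb in names(schema)) {
    if (is.null(registry[[tb]])) {
      stop("registry is missing table: ", tb, call. = FALSE)
    }
    miss <- setdiff(schema[[tb]], names(registry[[tb]]))
    if (length(miss)) {
      stop(sprintf("%s: missing column(s) %s", tb,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  known_drugs <- c(config$anti_vegf_drugs, "steroid", "other")
  bad <- which(!registry$injections$drug %in% known_drugs)
  if (length(bad)) {
    stop(sprintf("injections: unknown drug '%s' at row %d",
                 registry$injections$drug[bad[1]], bad[1]), call. = FALSE)
  }
  eye_tables <- c("injections", "va", "iop")
  for (tb in eye_tables) {
    orphan <- which(!registry[[tb]]$patient_id %in%
                      registry$patients$patient_id)
    if (length(orphan)) {
      stop(sprintf("%s: patient_id '%s' (row %d) not in patients", tb,
                   registry[[tb]]$patient_id[orphan[1]], orphan[1]),
           call. = FALSE)
    }
  }
  invisible(registry)
}

#' Load a registry from a directory of CSV files
#'
#' @param dir Directory holding the seven registry CSVs.
#' @param config A [criterion_config()] (drug vocabulary).
#' @return A validated object of class `registry`.
#' @export
load_registry <- function(dir, config = criterion_config()) {
  schema <- registry_schema()
  out <- list()
  for (tb in names(schema)) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      stop("missing registry file: ", path, call. = FALSE)
    }
    df <- read.csv(path, stringsAsFactors = FALSE)
    extra <- setdiff(names(df), schema[[tb]])
    if (length(extra)) {
      warning(sprintf("%s.csv: ignoring unknown column(s) %s", tb,
                      paste(extra, collapse = ", ")), call. = FALSE)
      df <- df[, intersect(names(df), schema[[tb]]), drop = FALSE]
    }
    miss <- setdiff(schema[[tb]], names(df))
    if (length(miss)) {
      stop(sprintf("%s.csv: missing column(s) %s", tb,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    if ("date" %in% names(df)) {
      df$date <- parse_date_column(df$date, paste0(tb, ".csv"))
    }
    if ("laterality" %in% names(df)) {
      df$laterality <- as.character(df$laterality)
      df$laterality[df$laterality == ""] <- NA_character_
    }
    out[[tb]] <- df[, schema[[tb]], drop = FALSE]
  }
  class(out) <- "registry"
  validate_registry(out, config)
  out
}

#' Write a fixture bundle (registry + trial roster + ground truth)
#'
#' @param dir Existing directory to write into (a missing directory is an
#'   error, not silently created).
#' @param registry A registry object.
#' @param trial Trial roster data.frame (all arms stacked), or NULL.
#' @param ground_truth Ground-truth manifest data.frame, or NULL.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(dir, registry, trial = NULL,
                                 ground_truth = NULL) {
  if (!dir.exists(dir)) {
    stop("directory does not exist: ", dir, call. = FALSE)
  }
  for (tb in names(registry_schema())) {
    write.csv(registry[[tb]], file.path(dir, paste0(tb, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  if (!is.null(trial)) {
    write.csv(trial, file.path(dir, "trial.csv"), row.names = FALSE,
              quote = FALSE)
  }
  if (!is.null(ground_truth)) {
    write.csv(ground_truth, file.path(dir, "ground_truth.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Load a trial roster CSV
#'
#' @param path CSV with columns `participant_id`, `arm`, `age`, `gender`,
#'   `baseline_letters`, `year1_letters`, `n_injections`,
#'   `endophthalmitis`.
#' @return data.frame.
#' @export
load_trial <- function(path) {
  need <- c("participant_id", "arm", "age", "gender", "baseline_letters",
            "year1_letters", "n_injections", "endophthalmitis")
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df$endophthalmitis <- as.logical(df$endophthalmitis)
  df
}
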