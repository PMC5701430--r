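#' EHR extract tables
#'
#' The pipeline consumes three comma-delimited UTF-8 tables with headers:
#'
#' * patients: `patient_id, birth_date, gender, ethnicity, death_date`
#'   (blank `death_date` allowed; an optional 0/1 `terminal_flag` column marks
#'   patients with a terminal-illness designation outside the diagnosis
#'   stream),
#' * diagnoses: `patient_id, code, system, date` with `system` one of
#'   `icd9`, `icd10`, `primary_care`,
#' * encounters: `patient_id, modality, start_date, end_date` with `modality`
#'   one of `inpatient`, `ED`, `specialist_clinic`, `primary_care`
#'   (`end_date` only for inpatient stays),
#'
#' and emits an assignments table
#' `patient_id, segment, n_conditions, index_year_admissions, rule_fired,
#' conditions_found` (the last a semicolon-joined condition list).  All dates
#' are ISO 8601 (`YYYY-MM-DD`).
#'
#' Readers run in lenient mode by default: malformed rows are dropped with a
#' row-numbered warning.  In strict mode any malformed row is an error.
#'
#' @name ehr_data
NULL

genders <- function() c("male", "female")
ethnicities <- function() c("chinese", "indian", "malay", "other")
modalities <- function() c("inpatient", "ED", "specialist_clinic", "primary_care")

read_delim_checked <- function(path, required, col_types) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  df
}

# Drop (lenient) or abort on (strict) rows flagged bad; reasons is a character
# vector with NA for good rows.
enforce_rows <- function(df, reasons, strict, what) {
  bad <- which(!is.na(reasons))
  if (length(bad) == 0) return(df)
  report <- sprintf("row %d: %s", bad, reasons[bad])
  msg <- sprintf("%s: %d malformed row(s)\n%s", what, length(bad),
                 paste(utils::head(report, 20), collapse = "\n"))
  if (strict) abort(msg)
  warn(paste0(msg, "\n(rows skipped; use strict = TRUE to make this fatal)"))
  df[-bad, , drop = FALSE]
}

parse_date_col <- function(x) {
  out <- as.Date(rep(NA_character_, length(x)))
  nz <- !is.na(x) & nzchar(x)
  # as.Date with an explicit format yields NA (not an error) on bad input
  out[nz] <- as.Date(x[nz], format = "%Y-%m-%d")
  out
}

#' Read a patients table
#'
#' @param path Path to a CSV file (see [ehr_data] for the schema).
#' @param strict If `TRUE`, malformed rows abort; otherwise they are skipped
#'   with a warning.
#' @return A tibble of patient records; `terminal_flag` is always present
#'   (filled with `FALSE` when the column is absent from the file).
#' @export
read_patients <- function(path, strict = FALSE) {
  df <- read_delim_checked(
    path, c("patient_id", "birth_date", "gender", "ethnicity", "death_date"),
    readr::cols(.default = readr::col_character()))
  birth <- parse_date_col(df$birth_date)
  death <- parse_date_col(df$death_date)
  has_death <- !is.na(df$death_date) & nzchar(df$death_date)
  reasons <- rep(NA_character_, nrow(df))
  reasons[is.na(df$patient_id) | !nzchar(df$patient_id)] <- "empty patient_id"
  reasons[is.na(birth)] <- "unparseable birth_date"
  reasons[has_death & is.na(death)] <- "unparseable death_date"
  reasons[!df$gender %in% genders()] <- "gender not male/female"
  reasons[!df$ethnicity %in% ethnicities()] <-
    "ethnicity not chinese/indian/malay/other"
  reasons[!is.na(death) & !is.na(birth) & death < birth] <-
    "death_date before birth_date"
  flag <- if ("terminal_flag" %in% names(df)) {
    df$terminal_flag %in% c("1", "TRUE", "true")
  } else rep(FALSE, nrow(df))
  out <- tibble::tibble(patient_id = df$patient_id, birth_date = birth,
                        gender = df$gender, ethnicity = df$ethnicity,
                        death_date = death, terminal_flag = flag)
  out <- enforce_rows(out, reasons, strict, "patients")
  dup <- out$patient_id[duplicated(out$patient_id)]
  if (length(dup) > 0) {
    abort(sprintf("patients: duplicate patient_id(s): %s",
                  paste(utils::head(unique(dup), 5), collapse = ", ")))
  }
  out
}

#' Read a diagnoses table
#'
#' @inheritParams read_patients
#' @return A tibble with columns `patient_id`, `code`, `system`, `date`.
#' @export
read_diagnoses <- function(path, strict = FALSE) {
  df <- read_delim_checked(path, c("patient_id", "code", "system", "date"),
                           readr::cols(.default = readr::col_character()))
  date <- parse_date_col(df$date)
  reasons <- rep(NA_character_, nrow(df))
  reasons[is.na(df$patient_id) | !nzchar(df$patient_id)] <- "empty patient_id"
  reasons[is.na(df$code) | !nzchar(trimws(df$code))] <- "empty code"
  reasons[!tolower(df$system) %in% catalog_systems()] <-
    "system not icd9/icd10/primary_care"
  reasons[is.na(date)] <- "unparseable date"
  out <- tibble::tibble(patient_id = df$patient_id, code = df$code,
                        system = tolower(df$system), date = date)
  enforce_rows(out, reasons, strict, "diagnoses")
}

#' Read an encounters table
#'
#' @inheritParams read_patients
#' @return A tibble with columns `patient_id`, `modality`, `start_date`,
#'   `end_date`.
#' @export
read_encounters <- function(path, strict = FALSE) {
  df <- read_delim_checked(
    path, c("patient_id", "modality", "start_date", "end_date"),
    readr::cols(.default = readr::col_character()))
  start <- parse_date_col(df$start_date)
  end <- parse_date_col(df$end_date)
  has_end <- !is.na(df$end_date) & nzchar(df$end_date)
  reasons <- rep(NA_character_, nrow(df))
  reasons[is.na(df$patient_id) | !nzchar(df$patient_id)] <- "empty patient_id"
  reasons[!df$modality %in% modalities()] <-
    "modality not inpatient/ED/specialist_clinic/primary_care"
  reasons[is.na(start)] <- "unparseable start_date"
  reasons[has_end & is.na(end)] <- "unparseable end_date"
  reasons[has_end & df$modality != "inpatient"] <-
    "end_date only allowed for inpatient encounters"
  reasons[!is.na(end) & !is.na(start) & end < start] <-
    "end_date before start_date"
  out <- tibble::tibble(patient_id = df$patient_id, modality = df$modality,
                        start_date = start, end_date = end)
  enforce_rows(out, reasons, strict, "encounters")
}

#' Write / read a segment-assignments table
#'
#' `write_assignments()` writes one row per patient with stable column order
#' (`patient_id, segment, n_conditions, index_year_admissions, rule_fired,
#' conditions_found`); `read_assignments()` reads it back, restoring the
#' `conditions_found` list-column, so that write-then-read is the identity.
#'
#' @param assignments A tibble as returned by [segment_cohort()].
#' @param path Output (or input) CSV path.
#' @return `write_assignments()` returns `path` invisibly;
#'   `read_assignments()` returns the assignments tibble.
#' @export
write_assignments <- function(assignments, path) {
  req <- c("patient_id", "segment", "index_year_admissions", "rule_fired")
  missing <- setdiff(req, names(assignments))
  if (length(missing) > 0) {
    abort(sprintf("assignments missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  assert_segments(assignments$segment)
  conds <- assignments$conditions_found %||%
    replicate(nrow(assignments), character(), simplify = FALSE)
  out <- tibble::tibble(
    patient_id = assignments$patient_id,
    segment = as.character(assignments$segment),
    n_conditions = lengths(conds),
    index_year_admissions = assignments$index_year_admissions,
    rule_fired = assignments$rule_fired,
    conditions_found = purrr::map_chr(conds, function(x)
      paste(sort(x), collapse = ";")))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  df <- read_delim_checked(
    path,
    c("patient_id", "segment", "n_conditions", "index_year_admissions",
      "rule_fired", "conditions_found"),
    readr::cols(patient_id = readr::col_character(),
                segment = readr::col_character(),
                n_conditions = readr::col_integer(),
                index_year_admissions = readr::col_integer(),
                rule_fired = readr::col_character(),
                conditions_found = readr::col_character()))
  assert_segments(df$segment)
  df$segment <- segment_factor(df$segment)
  df$conditions_found <- purrr::map(df$conditions_found, function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
  })
  df
}
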