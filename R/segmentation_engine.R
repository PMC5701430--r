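#' Segmentation engine
#'
#' The core computation: eligibility filtering, look-back condition
#' detection, merged-episode admission counting, and hierarchical segment
#' assignment.  [segment_cohort()] wires the stages together; the individual
#' operations are exported for inspection and testing.
#'
#' @name segmentation_engine
NULL

age_at_reference <- function(birth_date, index_year) {
  by <- lubridate::year(birth_date)
  # completed years at 1 January of the index year; a patient born after
  # 1 January has not yet had their birthday in the reference year
  index_year - by - as.integer(format(birth_date, "%m-%d") > "01-01")
}

lookback_window <- function(config) {
  c(as.Date(sprintf("%d-01-01", config$index_year - config$lookback_years + 1)),
    as.Date(sprintf("%d-12-31", config$index_year)))
}

#' Eligible cohort
#'
#' A patient is eligible when aged at least `min_age` completed years at
#' 1 January of the index year and having at least one encounter (of any
#' modality) starting in the index year.
#'
#' @param patients,encounters Tibbles in the [ehr_data] schemas.
#' @param config A [segmentation_config()].
#' @return Character vector of eligible patient ids.
#' @export
filter_eligible <- function(patients, encounters, config) {
  age <- age_at_reference(patients$birth_date, config$index_year)
  index_users <- unique(encounters$patient_id[
    lubridate::year(encounters$start_date) == config$index_year])
  patients$patient_id[age >= config$min_age &
                        patients$patient_id %in% index_users]
}

#' Detect chronic conditions for one patient
#'
#' Maps every diagnosis code dated inside the look-back window (the
#' `lookback_years` calendar years ending with the index year) against the
#' catalog and returns the union of matches.
#'
#' @param diagnoses Diagnosis records of a single patient.
#' @param catalog A [condition_catalog].
#' @param config A [segmentation_config()].
#' @return Sorted character vector of condition names.
#' @export
detect_conditions <- function(diagnoses, catalog, config) {
  if (length(unique(diagnoses$patient_id)) > 1) {
    abort("detect_conditions expects records of a single patient")
  }
  tbl <- detect_conditions_cohort(diagnoses, catalog, config)
  if (nrow(tbl) == 0) character() else tbl$conditions[[1]]
}

# Cohort-wide condition detection: tibble (patient_id, conditions list-col).
detect_conditions_cohort <- function(diagnoses, catalog, config) {
  win <- lookback_window(config)
  dx <- diagnoses[diagnoses$date >= win[1] & diagnoses$date <= win[2], ,
                  drop = FALSE]
  if (nrow(dx) == 0) {
    return(tibble::tibble(patient_id = character(), conditions = list()))
  }
  hits <- match_codes_bulk(dx$code, dx$system, catalog)
  if (nrow(hits) == 0) {
    return(tibble::tibble(patient_id = character(), conditions = list()))
  }
  matched <- tibble::tibble(patient_id = dx$patient_id[hits$idx],
                            condition = hits$condition)
  matched |>
    dplyr::distinct() |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(conditions = list(sort(.data$condition)),
                     .groups = "drop")
}

# Merge overlapping or abutting inpatient records (next start <= previous
# end + 1 day) into episodes; inter-facility transfers would otherwise
# double-count.  Returns one row per merged episode with its start date.
merge_inpatient_episodes <- function(encounters) {
  ip <- encounters[encounters$modality == "inpatient", , drop = FALSE]
  if (nrow(ip) == 0) {
    return(tibble::tibble(patient_id = character(),
                          episode_start = as.Date(character())))
  }
  s <- as.integer(ip$start_date)
  e <- as.integer(dplyr::coalesce(ip$end_date, ip$start_date))
  e <- pmax(s, e)
  ord <- order(ip$patient_id, s)
  pid <- ip$patient_id[ord]; s <- s[ord]; e <- e[ord]
  same <- c(FALSE, pid[-1] == pid[-length(pid)])
  # running maximum of record end within patient (ordered by start)
  run_max <- stats::ave(e, cumsum(!same), FUN = cummax)
  prev_max <- c(NA_integer_, run_max[-length(run_max)])
  for_new <- !same | s > prev_max + 1L
  tibble::tibble(patient_id = pid[for_new],
                 episode_start = as.Date(s[for_new], origin = "1970-01-01"))
}

#' Count inpatient admissions for one patient in a calendar year
#'
#' Overlapping or same-day-contiguous inpatient records are merged into a
#' single episode before counting; an episode is attributed to the year of
#' its (merged) start date.
#'
#' @param encounters Encounter records of a single patient.
#' @param year Calendar year.
#' @return Non-negative integer count of merged admissions.
#' @export
count_admissions <- function(encounters, year) {
  if (length(unique(encounters$patient_id)) > 1) {
    abort("count_admissions expects records of a single patient")
  }
  ep <- merge_inpatient_episodes(encounters)
  as.integer(sum(lubridate::year(ep$episode_start) == year))
}

# Per-patient admission (and ED-visit) counts for the index year.
count_utilization_cohort <- function(encounters, config) {
  ep <- merge_inpatient_episodes(encounters)
  ep <- ep[lubridate::year(ep$episode_start) == config$index_year, ,
           drop = FALSE]
  adm <- dplyr::count(ep, .data$patient_id, name = "admissions")
  ed <- encounters[encounters$modality == "ED" &
                     lubridate::year(encounters$start_date) ==
                       config$index_year, , drop = FALSE]
  ed <- dplyr::count(ed, .data$patient_id, name = "ed_visits")
  dplyr::full_join(adm, ed, by = "patient_id")
}

rule_labels <- function() {
  c(end_of_life = "terminal_condition_or_flag",
    complex_freq = "complex_condition_and_frequent_admissions",
    complex_no_freq = "complex_condition",
    serious_acute = "index_year_admission",
    stable_chronic = "stable_condition_only",
    mostly_healthy = "no_chronic_condition_no_admission")
}

# Vectorized rule evaluation in precedence order; first match wins.
apply_rules <- function(has_stable, has_complex, has_terminal, admissions,
                        ed_visits, terminal_flag, config) {
  n <- length(admissions)
  thr <- config$frequent_admission_threshold
  acute <- admissions >= 1
  if (config$serious_acute_includes_ed) acute <- acute | ed_visits >= 1
  preds <- list(
    end_of_life = has_terminal | terminal_flag,
    complex_freq = has_complex & admissions >= thr,
    complex_no_freq = has_complex,
    serious_acute = acute,
    stable_chronic = has_stable,
    mostly_healthy = rep(TRUE, n))
  seg <- rep(NA_character_, n)
  rule <- rep(NA_character_, n)
  labels <- rule_labels()
  for (s in config$precedence) {
    sel <- is.na(seg) & preds[[s]]
    seg[sel] <- s
    rule[sel] <- labels[[s]]
  }
  list(segment = seg, rule_fired = rule)
}

#' Assign a segment to one patient
#'
#' Applies the precedence rules: (1) any terminal condition (or terminal
#' flag) gives end-of-life; (2) any complex condition together with at least
#' `frequent_admission_threshold` index-year admissions gives complex
#' chronic with frequent admissions; (3) any complex condition gives complex
#' chronic without frequent admissions; (4) at least one index-year
#' admission gives serious acute illness; (5) any stable condition gives
#' stable chronic; (6) otherwise mostly healthy.
#'
#' @param conditions Character vector of condition names (from
#'   [detect_conditions()]).
#' @param catalog A [condition_catalog]; every name in `conditions` must be
#'   present in it.
#' @param index_admissions Merged inpatient episode count in the index year.
#' @param config A [segmentation_config()].
#' @param terminal_flag Optional per-patient terminal-illness designation
#'   (see [ehr_data]).
#' @param ed_visits Index-year ED visit count (used only when
#'   `serious_acute_includes_ed` is enabled).
#' @return A list with elements `segment` and `rule_fired`.
#' @examples
#' cfg <- segmentation_config()
#' cat34 <- default_catalog()
#' assign_segment(c("hypertension", "hyperlipidemia"), cat34, 0, cfg)$segment
#' assign_segment("atrial_fibrillation", cat34, 4, cfg)$segment
#' @export
assign_segment <- function(conditions, catalog, index_admissions, config,
                           terminal_flag = FALSE, ed_visits = 0) {
  unknown <- setdiff(conditions, catalog$name)
  if (length(unknown) > 0) {
    abort(sprintf("condition(s) not in catalog: %s",
                  paste(unknown, collapse = ", ")))
  }
  cats <- catalog$category[match(conditions, catalog$name)]
  res <- apply_rules(any(cats == "stable"), any(cats == "complex"),
                     any(cats == "terminal"), index_admissions, ed_visits,
                     terminal_flag, config)
  list(segment = res$segment, rule_fired = res$rule_fired)
}

#' Segment a cohort
#'
#' Runs the full pipeline: eligibility filtering, look-back condition
#' detection, index-year admission counting with episode merging, and
#' precedence-rule assignment.  Exactly one assignment is produced per
#' eligible patient.
#'
#' @param patients,diagnoses,encounters Tibbles in the [ehr_data] schemas.
#' @param catalog A [condition_catalog].
#' @param config A [segmentation_config()].
#' @param verbose If `TRUE`, per-segment and per-rule counts are reported
#'   via `message()`.
#' @return A tibble with one row per eligible patient: `patient_id`,
#'   `segment` (factor), `conditions_found` (list-column),
#'   `index_year_admissions`, `rule_fired`.
#' @examples
#' cohort <- generate_cohort(default_generator_config(500, seed = 7))
#' asg <- segment_cohort(cohort$patients, cohort$diagnoses,
#'                       cohort$encounters, default_catalog(),
#'                       segmentation_config())
#' table(asg$segment)
#' @export
segment_cohort <- function(patients, diagnoses, encounters, catalog, config,
                           verbose = FALSE) {
  eligible <- filter_eligible(patients, encounters, config)
  if (length(eligible) == 0) {
    return(tibble::tibble(patient_id = character(),
                          segment = segment_factor(character()),
                          conditions_found = list(),
                          index_year_admissions = integer(),
                          rule_fired = character()))
  }
  dx <- diagnoses[diagnoses$patient_id %in% eligible, , drop = FALSE]
  cond_tbl <- detect_conditions_cohort(dx, catalog, config)
  util <- count_utilization_cohort(
    encounters[encounters$patient_id %in% eligible, , drop = FALSE], config)

  base <- tibble::tibble(patient_id = eligible)
  base <- dplyr::left_join(base, cond_tbl, by = "patient_id")
  base <- dplyr::left_join(base, util, by = "patient_id")
  base$conditions_found <- purrr::map(base$conditions, ~ .x %||% character())
  base$admissions <- dplyr::coalesce(base$admissions, 0L)
  base$ed_visits <- dplyr::coalesce(base$ed_visits, 0L)

  flag <- patients$terminal_flag %||% rep(FALSE, nrow(patients))
  base$terminal_flag <- flag[match(base$patient_id, patients$patient_id)]

  cat_of <- function(category) {
    nms <- catalog$name[catalog$category == category]
    purrr::map_lgl(base$conditions_found, ~ any(.x %in% nms))
  }
  unknown <- setdiff(unique(unlist(base$conditions_found)), catalog$name)
  if (length(unknown) > 0) {
    abort(sprintf("condition(s) not in catalog: %s",
                  paste(unknown, collapse = ", ")))
  }
  res <- apply_rules(cat_of("stable"), cat_of("complex"), cat_of("terminal"),
                     base$admissions, base$ed_visits, base$terminal_flag,
                     config)
  out <- tibble::tibble(patient_id = base$patient_id,
                        segment = segment_factor(res$segment),
                        conditions_found = base$conditions_found,
                        index_year_admissions = as.integer(base$admissions),
                        rule_fired = res$rule_fired)
  if (verbose) {
    counts <- table(out$segment)
    message("segment counts: ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
    rules <- table(out$rule_fired)
    message("rule counts: ",
            paste(sprintf("%s=%d", names(rules), rules), collapse = ", "))
  }
  out
}
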