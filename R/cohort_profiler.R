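#' Segment profiling
#'
#' Reproduces the study's output surface: per-segment descriptive tables
#' (demographics, index-year utilization and mortality, condition
#' prevalence), printed-rate arithmetic, chi-square and one-way ANOVA
#' comparisons across segments, and truth-recovery reports.
#'
#' @name cohort_profiler
NULL

#' Percent from a count pair, as printed
#'
#' `100 * numerator / denominator`, rounded half away from zero to the
#' requested number of decimals — the convention used by the published
#' "number (%)" table cells.
#'
#' @param numerator,denominator Counts with `0 <= numerator <= denominator`
#'   and `denominator > 0`.
#' @param decimals Decimal places (default 1).
#' @return The rounded percentage.
#' @examples
#' rate_from_counts(769, 4705, 0)   # 16
#' rate_from_counts(2540, 4705, 1)  # 54.0
#' @export
rate_from_counts <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) abort("denominator must be positive")
  if (any(numerator < 0 | numerator > denominator)) {
    abort("numerator must lie in [0, denominator]")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction, with expected counts
#' from the row/column margins and `df = (r-1)(c-1)`.
#'
#' @param contingency Numeric matrix of counts, at least 2x2, with no
#'   all-zero row or column.
#' @return A `stat_test` list: `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_test(matrix(c(10, 0, 0, 10), 2))
#' @export
chi_square_test <- function(contingency) {
  m <- as.matrix(contingency)
  if (nrow(m) < 2 || ncol(m) < 2) abort("contingency table must be at least 2x2")
  if (any(m < 0)) abort("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("degenerate margins: all-zero row or column")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  new_stat_test(unname(res$statistic), unname(res$parameter),
                unname(res$p.value), "chi-square")
}

#' One-way ANOVA across groups
#'
#' F = MS_between / MS_within with df (k-1, N-k).  When the within-group
#' mean square is zero the statistic is reported as `Inf` with p = 0 if the
#' groups differ, and as 0 with p = 1 when all values are identical.
#'
#' @param groups A list of at least two numeric vectors, each non-empty,
#'   with total within-group degrees of freedom of at least one.
#' @return A `stat_test` list: `statistic`, `df` (length 2), `p_value`.
#' @examples
#' one_way_anova(list(c(0, 2), c(2, 4)))
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("need at least two groups")
  if (any(lengths(groups) == 0)) abort("every group needs at least one value")
  n <- lengths(groups)
  N <- sum(n); k <- length(groups)
  if (N - k < 1) abort("total within-group degrees of freedom must be >= 1")
  values <- unlist(groups)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n * (means - mean(values))^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  df <- c(k - 1, N - k)
  if (ss_within == 0) {
    if (ss_between > 0) return(new_stat_test(Inf, df, 0, "one-way ANOVA"))
    return(new_stat_test(0, df, 1, "one-way ANOVA"))
  }
  f <- (ss_between / df[1]) / (ss_within / df[2])
  new_stat_test(f, df, stats::pf(f, df[1], df[2], lower.tail = FALSE),
                "one-way ANOVA")
}

new_stat_test <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method), class = "stat_test")
}

#' @export
print.stat_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p %s\n", x$method, x$statistic,
              paste(x$df, collapse = ", "), format_p(x$p_value)))
  invisible(x)
}

# published tables render small p-values as "<0.001"; full precision is kept
# in the object
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("= %.3f", p))
}

#' Profile a segmented cohort
#'
#' Builds the per-segment descriptive tables: segment sizes and demographics
#' (age groups, gender, ethnicity), index-year utilization means/SDs by
#' modality with mortality counts, and condition prevalence, each mirroring
#' the published table layouts.  Chi-square tests compare categorical rows
#' and one-way ANOVA the utilization counts across segments.
#'
#' @param assignments Assignment tibble from [segment_cohort()] (or
#'   [read_assignments()]).
#' @param patients,encounters Tibbles in the [ehr_data] schemas; every
#'   assigned patient must appear in `patients`.
#' @param catalog A [condition_catalog].
#' @param config A [segmentation_config()]; fixes the index year for the
#'   utilization and mortality columns.
#' @param tests If `TRUE` (default), append across-segment test statistics.
#' @return A `segment_profile` list of tibbles: `segments`, `demographics`,
#'   `utilization`, `prevalence`.
#' @export
profile_segments <- function(assignments, patients, encounters, catalog,
                             config, tests = TRUE) {
  if (nrow(assignments) == 0) abort("assignments are empty")
  missing <- setdiff(assignments$patient_id, patients$patient_id)
  if (length(missing) > 0) {
    abort(sprintf("assignment(s) reference unknown patient(s), e.g. %s",
                  missing[1]))
  }
  seg <- segment_factor(as.character(assignments$segment))
  n_total <- nrow(assignments)
  iy <- config$index_year
  pm <- match(assignments$patient_id, patients$patient_id)

  seg_n <- as.integer(table(seg))
  segments <- tibble::tibble(
    segment = segment_levels(), n = seg_n,
    percent = rate_from_counts(seg_n, n_total, 1))

  age <- age_at_reference(patients$birth_date[pm], iy)
  grp <- cut(age, breaks = c(-Inf, 39, 64, 84, Inf),
             labels = names(age_group_ranges()))
  demo_rows <- list(
    age_group = table(grp, seg),
    gender = table(factor(patients$gender[pm], genders()), seg),
    ethnicity = table(factor(patients$ethnicity[pm], ethnicities()), seg))
  demographics <- purrr::imap_dfr(demo_rows, function(tab, var) {
    counts <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(counts) <- c("level", "segment", "count")
    counts$segment <- as.character(counts$segment)
    counts$variable <- var
    counts <- dplyr::left_join(counts, segments[c("segment", "n")],
                               by = "segment")
    counts$percent <- ifelse(counts$n > 0,
                             rate_from_counts(counts$count,
                                              pmax(counts$n, 1), 1), NA_real_)
    p <- NA_real_
    if (isTRUE(tests)) {
      keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
      if (sum(keep_r) >= 2 && sum(keep_c) >= 2) {
        p <- chi_square_test(tab[keep_r, keep_c, drop = FALSE])$p_value
      }
    }
    counts$p_value <- p
    tibble::as_tibble(counts[c("variable", "level", "segment", "count",
                               "percent", "p_value")])
  })

  util <- index_year_counts(assignments$patient_id, encounters, iy)
  utilization <- purrr::map_dfr(
    c(ed_visits = "ed_visits", specialist_visits = "specialist_visits",
      admissions = "admissions"),
    function(col) {
      by_seg <- split(util[[col]], seg)
      p <- NA_real_
      if (isTRUE(tests)) {
        nonempty <- by_seg[lengths(by_seg) > 0]
        if (length(nonempty) >= 2 && sum(lengths(nonempty)) >
            length(nonempty)) {
          p <- one_way_anova(nonempty)$p_value
        }
      }
      tibble::tibble(variable = col, segment = segment_levels(),
                     mean = unname(vapply(by_seg, function(x)
                       if (length(x)) mean(x) else NA_real_, numeric(1))),
                     sd = unname(vapply(by_seg, function(x)
                       if (length(x) > 1) stats::sd(x) else NA_real_,
                       numeric(1))),
                     p_value = p)
    })
  dead <- !is.na(patients$death_date[pm]) &
    lubridate::year(patients$death_date[pm]) == iy
  mort_tab <- table(factor(dead, c(FALSE, TRUE)), seg)
  mort_p <- NA_real_
  if (isTRUE(tests) && all(rowSums(mort_tab) > 0)) {
    keep_c <- colSums(mort_tab) > 0
    if (sum(keep_c) >= 2) {
      mort_p <- chi_square_test(mort_tab[, keep_c, drop = FALSE])$p_value
    }
  }
  utilization <- dplyr::bind_rows(
    utilization,
    tibble::tibble(variable = "mortality", segment = segment_levels(),
                   mean = NA_real_, sd = NA_real_, p_value = mort_p,
                   count = as.integer(mort_tab["TRUE", ]),
                   percent = ifelse(seg_n > 0,
                                    rate_from_counts(
                                      as.integer(mort_tab["TRUE", ]),
                                      pmax(seg_n, 1), 1), NA_real_)))

  conds <- assignments$conditions_found %||%
    replicate(n_total, character(), simplify = FALSE)
  n_cond <- lengths(conds)
  cond_long <- tibble::tibble(segment = rep(as.character(seg), n_cond),
                              condition = unlist(conds))
  prevalence <- tidyr::crossing(condition = catalog$name,
                                segment = segment_levels())
  cc <- dplyr::count(cond_long, .data$condition, .data$segment)
  prevalence <- dplyr::left_join(prevalence, cc,
                                 by = c("condition", "segment"))
  prevalence$n <- dplyr::coalesce(prevalence$n, 0L)
  names(prevalence)[names(prevalence) == "n"] <- "count"
  seg_sizes <- stats::setNames(seg_n, segment_levels())
  prevalence$segment_n <- unname(seg_sizes[prevalence$segment])
  prevalence$percent <- ifelse(prevalence$segment_n > 0,
                               rate_from_counts(prevalence$count,
                                                pmax(prevalence$segment_n, 1),
                                                1), NA_real_)
  prevalence <- prevalence[order(match(prevalence$condition, catalog$name),
                                 match(prevalence$segment,
                                       segment_levels())), ]
  mean_conditions <- tibble::tibble(
    segment = segment_levels(),
    mean = unname(vapply(split(n_cond, seg), function(x)
      if (length(x)) mean(x) else NA_real_, numeric(1))),
    sd = unname(vapply(split(n_cond, seg), function(x)
      if (length(x) > 1) stats::sd(x) else NA_real_, numeric(1))))

  structure(list(n = n_total, index_year = iy, segments = segments,
                 demographics = demographics, utilization = utilization,
                 mean_conditions = mean_conditions,
                 prevalence = tibble::as_tibble(prevalence)),
            class = "segment_profile")
}

# per-patient index-year counts (ED, specialist, merged admissions) aligned
# to the given patient ids
index_year_counts <- function(patient_ids, encounters, index_year) {
  enc <- encounters[lubridate::year(encounters$start_date) == index_year, ,
                    drop = FALSE]
  count_mod <- function(mod) {
    tab <- table(enc$patient_id[enc$modality == mod])
    out <- as.integer(tab[patient_ids])
    dplyr::coalesce(out, 0L)
  }
  ep <- merge_inpatient_episodes(encounters)
  ep <- ep[lubridate::year(ep$episode_start) == index_year, , drop = FALSE]
  adm_tab <- table(ep$patient_id)
  tibble::tibble(patient_id = patient_ids,
                 ed_visits = count_mod("ED"),
                 specialist_visits = count_mod("specialist_clinic"),
                 admissions = dplyr::coalesce(
                   as.integer(adm_tab[patient_ids]), 0L))
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("<segment_profile> %d patients, index year %d\n", x$n,
              x$index_year))
  print(x$segments)
  invisible(x)
}

#' Write profile tables to a directory
#'
#' Writes the profile as tab-separated tables (`segments.tsv`,
#' `demographics.tsv`, `utilization.tsv`, `mean_conditions.tsv`,
#' `prevalence.tsv`) plus a machine-readable `profile.json`.
#'
#' @param profile A `segment_profile`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_profile <- function(profile, dir) {
  stopifnot(inherits(profile, "segment_profile"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("segments", "demographics", "utilization", "mean_conditions",
               "prevalence")) {
    readr::write_tsv(profile[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  jsonlite::write_json(unclass(profile), file.path(dir, "profile.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Truth-recovery report
#'
#' Confusion matrix of truth segments against assigned segments, with
#' overall accuracy (trace over total).
#'
#' @param truth Tibble with `patient_id` and `segment` (the generator's
#'   truth labels).
#' @param assignments Assignment tibble covering the same patients.
#' @return A `recovery_report` list: `confusion` (6x6 matrix, truth in rows),
#'   `accuracy`, `n`.
#' @examples
#' cohort <- generate_cohort(default_generator_config(300, seed = 9))
#' asg <- segment_cohort(cohort$patients, cohort$diagnoses,
#'                       cohort$encounters, default_catalog(),
#'                       segmentation_config())
#' recovery_report(cohort$truth, asg)$accuracy
#' @export
recovery_report <- function(truth, assignments) {
  if (!setequal(truth$patient_id, assignments$patient_id)) {
    abort("truth and assignments must cover the same patient ids")
  }
  m <- match(truth$patient_id, assignments$patient_id)
  confusion <- table(truth = segment_factor(as.character(truth$segment)),
                     assigned = segment_factor(
                       as.character(assignments$segment[m])))
  structure(list(confusion = unclass(confusion),
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 n = sum(confusion)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d patients, accuracy %.4f\n", x$n,
              x$accuracy))
  print(x$confusion)
  invisible(x)
}
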