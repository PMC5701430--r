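#' Synthetic cohort generation
#'
#' Generates a synthetic regional-health-system population with known truth
#' segments, calibrated to the published per-segment demographics,
#' utilization, mortality and condition-prevalence tables, so that the whole
#' pipeline can be validated without access to any real EHR.  Each patient
#' is constructed to satisfy their truth segment's defining rule and no
#' higher-precedence rule, making truth-label recovery by [segment_cohort()]
#' exact.
#'
#' @name synthetic_cohort
NULL

#' Count-distribution constraints
#'
#' Structural constraints the generator imposes on utilization counts:
#' `"none"`, `"zero"` (count is structurally 0), `"at_least"` / `"at_most"`
#' with bound `k`.
#'
#' @param type One of `"none"`, `"zero"`, `"at_least"`, `"at_most"`.
#' @param k Bound for `at_least` / `at_most`.
#' @return A `count_constraint` list.
#' @export
count_constraint <- function(type = c("none", "zero", "at_least", "at_most"),
                             k = NULL) {
  type <- match.arg(type)
  if (type %in% c("at_least", "at_most")) {
    if (is.null(k) || k < 0) abort(sprintf("constraint '%s' needs a bound k >= 0", type))
    k <- as.integer(k)
  } else {
    k <- NULL
  }
  structure(list(type = type, k = k), class = "count_constraint")
}

# Negative binomial by method of moments (size = mu^2 / (sd^2 - mu)),
# Poisson fallback when the variance does not exceed the mean.
nb_or_pois <- function(n, mean, sd) {
  if (n == 0) return(integer())
  if (mean <= 0) return(rep(0L, n))
  if (sd^2 > mean) {
    size <- mean^2 / (sd^2 - mean)
    as.integer(rnbinom(n, size = size, mu = mean))
  } else {
    as.integer(rpois(n, mean))
  }
}

#' Draw utilization counts
#'
#' Draws `n` non-negative integers with the requested mean and standard
#' deviation: negative binomial fitted by method of moments when the
#' variance exceeds the mean, Poisson otherwise.  An `at_least(k)`
#' constraint is met by drawing `k` plus a moment-matched residual (so the
#' target mean and SD are preserved); `at_most(k)` by rejection; `zero`
#' requires a zero mean.
#'
#' @param n Number of draws.
#' @param mean,sd Target moments (`mean >= 0`, `sd >= 0`).
#' @param constraint A [count_constraint()].
#' @return Integer vector of length `n`.
#' @examples
#' x <- sample_count(1000, 4.33, 2.12, count_constraint("at_least", 3))
#' all(x >= 3)
#' @export
sample_count <- function(n, mean, sd, constraint = count_constraint("none")) {
  stopifnot(inherits(constraint, "count_constraint"), mean >= 0, sd >= 0)
  switch(constraint$type,
    none = nb_or_pois(n, mean, sd),
    zero = {
      if (mean > 0) abort("infeasible constraint: zero count with mean > 0")
      rep(0L, n)
    },
    at_least = {
      if (mean < constraint$k) {
        abort(sprintf("infeasible constraint: at_least(%d) with mean %g",
                      constraint$k, mean))
      }
      constraint$k + nb_or_pois(n, mean - constraint$k, sd)
    },
    at_most = {
      x <- nb_or_pois(n, mean, sd)
      repeat {
        bad <- which(x > constraint$k)
        if (length(bad) == 0) break
        x[bad] <- nb_or_pois(length(bad), mean, sd)
      }
      x
    })
}

# For a prevalence vector p with sum(p) > 1, find sampling probabilities
# q = p * t such that after conditioning on at least one success the
# marginals equal p exactly: t solves 1 - prod(1 - p t) = t.
solve_conditional_scaling <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0 || sum(p) <= 1) return(NA_real_)
  f <- function(t) (1 - prod(1 - p * t)) - t
  stats::uniroot(f, c(1e-9, 1 - 1e-12), tol = 1e-12)$root
}

#' Default calibrated generator configuration
#'
#' Builds the shipped calibration: segment proportions from the published
#' segment counts (summing to one exactly), per-segment age-group, gender
#' and ethnicity distributions, per-segment utilization count moments with
#' the structural admission constraints of each segment (mostly healthy and
#' stable chronic: zero admissions; serious acute: at least one; complex
#' without frequent admissions: at most threshold-1; complex with frequent
#' admissions: at least threshold), per-segment mortality, and a
#' condition-prevalence matrix derived from the published segment-by-disease
#' table.
#'
#' Two consistency edits reconcile the published prevalence columns with the
#' segments' defining rules (see the methods vignette): complex-defining and
#' terminal conditions are zeroed outside the segments they define, and in
#' the two complex segments the stable-condition prevalences are rescaled so
#' the expected condition count equals the published per-segment mean after
#' conditioning on at least one complex condition.  End-of-life membership
#' is marked with the per-patient terminal flag, leaving that segment's
#' prevalence column untouched.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; generation is deterministic given
#'   `(seed, n_patients)`.
#' @param index_year Index calendar year (default 2012).
#' @param catalog Condition catalog used for categories and code patterns.
#' @param segmentation A [segmentation_config()]; supplies the look-back and
#'   the frequent-admission threshold the structural constraints honour.
#' @return A `generator_config` list.
#' @export
default_generator_config <- function(n_patients, seed = 42,
                                     index_year = 2012,
                                     catalog = default_catalog(),
                                     segmentation = segmentation_config(
                                       index_year = index_year)) {
  if (n_patients < 1) abort("n_patients must be >= 1")
  cal <- reference_calibration()
  segs <- segment_levels()
  thr <- segmentation$frequent_admission_threshold

  stable_names <- catalog$name[catalog$category == "stable"]
  complex_names <- catalog$name[catalog$category == "complex"]
  terminal_names <- catalog$name[catalog$category == "terminal"]

  prev <- matrix(0, nrow = nrow(catalog), ncol = length(segs),
                 dimnames = list(catalog$name, segs))
  for (s in colnames(cal$prevalence_counts)) {
    p <- cal$prevalence_counts[, s] / cal$segment_counts[[s]]
    prev[names(p), s] <- p
  }
  # conditions that would fire a higher-precedence rule are zeroed outside
  # the segments they define
  prev[c(complex_names, terminal_names), "stable_chronic"] <- 0
  prev[terminal_names, c("complex_no_freq", "complex_freq")] <- 0

  at_least_one <- list(mostly_healthy = character(),
                       serious_acute = character(),
                       stable_chronic = stable_names,
                       complex_no_freq = complex_names,
                       complex_freq = complex_names,
                       end_of_life = character())

  # stable_chronic: rescale so that conditioning on >=1 stable condition
  # reproduces the published marginals exactly (possible because they sum
  # to more than one)
  t_sc <- solve_conditional_scaling(prev[stable_names, "stable_chronic"])
  if (!is.na(t_sc)) {
    prev[stable_names, "stable_chronic"] <-
      prev[stable_names, "stable_chronic"] * t_sc
  }
  # complex segments: published complex-condition prevalences sum to < 1 so
  # exact marginals are unattainable under the >=1-complex requirement;
  # keep them as sampling probabilities (conditioning inflates them) and
  # rescale the stable conditions so the expected condition count matches
  # the published per-segment mean
  for (s in c("complex_no_freq", "complex_freq")) {
    pc <- prev[complex_names, s]
    e_complex <- sum(pc) / (1 - prod(1 - pc))
    p_stable <- prev[stable_names, s]
    target <- cal$mean_conditions[[s]] - e_complex
    if (sum(p_stable) > 0 && target > 0) {
      prev[stable_names, s] <- p_stable * (target / sum(p_stable))
    }
  }

  named <- function(x) stats::setNames(x, segs)
  norm_cols <- function(m) sweep(m, 2, colSums(m), "/")
  util <- purrr::map(segs, function(s) {
    list(ed = c(mean = cal$utilization$ed_visits$mean[[s]],
                sd = cal$utilization$ed_visits$sd[[s]]),
         specialist = c(mean = cal$utilization$specialist_visits$mean[[s]],
                        sd = cal$utilization$specialist_visits$sd[[s]]),
         admissions = c(mean = cal$utilization$admissions$mean[[s]],
                        sd = cal$utilization$admissions$sd[[s]]))
  })
  names(util) <- segs
  adm_constraint <- list(
    mostly_healthy = count_constraint("zero"),
    serious_acute = count_constraint("at_least", 1),
    stable_chronic = count_constraint("zero"),
    complex_no_freq = count_constraint("at_most", thr - 1),
    complex_freq = count_constraint("at_least", thr),
    end_of_life = count_constraint("none"))

  config <- structure(list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    index_year = as.integer(index_year),
    lookback_years = segmentation$lookback_years,
    segment_proportions = cal$segment_counts / cal$cohort_total,
    age_group_distributions = norm_cols(cal$age_counts),
    male_fraction = cal$male_counts / cal$segment_counts,
    ethnicity_distribution = norm_cols(cal$ethnicity_counts),
    prevalence_matrix = prev,
    at_least_one = at_least_one,
    utilization_params = util,
    admission_constraint = adm_constraint,
    mortality_prob = cal$mortality_counts / cal$segment_counts,
    terminal_flag_segment = "end_of_life",
    catalog = catalog), class = "generator_config")
  validate_generator_config(config)
  config
}

validate_generator_config <- function(config) {
  p <- config$segment_proportions
  if (abs(sum(p) - 1) > 1e-9) abort("segment_proportions must sum to 1")
  if (any(p < 0)) abort("segment_proportions must be non-negative")
  if (any(config$prevalence_matrix < 0 | config$prevalence_matrix > 1)) {
    abort("prevalence_matrix entries must be probabilities")
  }
  if (any(config$mortality_prob < 0 | config$mortality_prob > 1)) {
    abort("mortality_prob entries must be probabilities")
  }
  for (s in segment_levels()) {
    u <- config$utilization_params[[s]]
    if (any(c(u$ed, u$specialist, u$admissions) < 0)) {
      abort(sprintf("utilization parameters for %s must be non-negative", s))
    }
    con <- config$admission_constraint[[s]]
    m <- u$admissions[["mean"]]
    if (con$type == "at_least" && m < con$k) {
      abort(sprintf("segment %s: admission mean %g infeasible under at_least(%d)",
                    s, m, con$k))
    }
    if (con$type == "zero" && m > 0) {
      abort(sprintf("segment %s: admission mean %g infeasible under zero constraint",
                    s, m))
    }
    need <- config$at_least_one[[s]]
    if (length(need) > 0 && sum(config$prevalence_matrix[need, s]) == 0) {
      abort(sprintf("segment %s: at-least-one condition set has zero total prevalence",
                    s))
    }
  }
  invisible(config)
}

#' Effective condition prevalence implied by a generator config
#'
#' The prevalence matrix in a [default_generator_config()] stores sampling
#' probabilities; for segments that require at least one condition of a
#' given class, rejection conditioning inflates the marginal prevalence of
#' that class.  This returns the implied marginal prevalence per condition
#' and segment, and is what empirical cohort prevalences should be compared
#' against.
#'
#' @param config A `generator_config`.
#' @return Matrix (conditions x segments) of expected marginal prevalences.
#' @export
expected_prevalence <- function(config) {
  eff <- config$prevalence_matrix
  for (s in colnames(eff)) {
    need <- config$at_least_one[[s]]
    need <- need[config$prevalence_matrix[need, s] > 0]
    if (length(need) > 0) {
      p1 <- 1 - prod(1 - eff[need, s])
      eff[need, s] <- eff[need, s] / p1
    }
  }
  eff
}

#' @rdname expected_prevalence
#' @export
expected_mean_conditions <- function(config) {
  colSums(expected_prevalence(config))
}

age_group_ranges <- function() {
  list("21-39" = c(21L, 39L), "40-64" = c(40L, 64L),
       "65-84" = c(65L, 84L), "85+" = c(85L, 100L))
}

# Bernoulli condition matrix for one segment, conditioned (by rejection) on
# at least one success among `need_idx` when that set is non-empty.
draw_condition_matrix <- function(n_g, p, need_idx) {
  k <- length(p)
  m <- matrix(runif(n_g * k) < rep(p, each = n_g), nrow = n_g)
  if (length(need_idx) > 0 && n_g > 0) {
    if (sum(p[need_idx]) == 0) {
      abort("at-least-one constraint infeasible: all target prevalences zero")
    }
    repeat {
      bad <- which(rowSums(m[, need_idx, drop = FALSE]) == 0)
      if (length(bad) == 0) break
      m[bad, need_idx] <-
        matrix(runif(length(bad) * length(need_idx)) <
                 rep(p[need_idx], each = length(bad)), nrow = length(bad))
    }
  }
  m
}

#' Generate a synthetic cohort
#'
#' Draws a population under a generator configuration: truth segments from
#' the segment proportions; demographics from the per-segment distributions;
#' condition sets from the prevalence matrix under each segment's structural
#' constraints; one dated diagnosis record per condition with a code drawn
#' from the catalog's patterns inside the look-back window; index-year
#' encounter streams with counts from [sample_count()] under the segment's
#' admission constraint (inpatient episodes are placed so that they never
#' merge, preserving the drawn admission count); a primary-care visit when a
#' patient would otherwise have no index-year encounter; and an index-year
#' death date with the segment's mortality probability.  Deterministic given
#' `(seed, n_patients)`.
#'
#' @param config A `generator_config` from [default_generator_config()].
#' @return A `synthetic_cohort` list with elements `patients`, `diagnoses`,
#'   `encounters` (tibbles in the [ehr_data] schemas) and `truth`
#'   (`patient_id`, `segment`).
#' @examples
#' cohort <- generate_cohort(default_generator_config(200, seed = 1))
#' table(cohort$truth$segment)
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  segs <- segment_levels()
  iy <- config$index_year
  year_start <- as.Date(sprintf("%d-01-01", iy))
  catalog <- config$catalog

  seg <- sample(segs, n, replace = TRUE, prob = config$segment_proportions)
  pid <- sprintf("P%07d", seq_len(n))

  age <- integer(n); male <- logical(n); eth <- character(n)
  conds <- vector("list", n)
  ed_n <- integer(n); soc_n <- integer(n); adm_n <- integer(n)
  died <- logical(n)
  ranges <- age_group_ranges()

  for (s in segs) {
    idx <- which(seg == s)
    n_g <- length(idx)
    if (n_g == 0) next
    grp <- sample(names(ranges), n_g, replace = TRUE,
                  prob = config$age_group_distributions[, s])
    lo <- vapply(ranges, `[[`, integer(1), 1)[grp]
    hi <- vapply(ranges, `[[`, integer(1), 2)[grp]
    age[idx] <- lo + as.integer(floor(runif(n_g) * (hi - lo + 1)))
    male[idx] <- runif(n_g) < config$male_fraction[[s]]
    eth[idx] <- sample(rownames(config$ethnicity_distribution), n_g,
                       replace = TRUE,
                       prob = config$ethnicity_distribution[, s])
    p <- config$prevalence_matrix[, s]
    need_idx <- match(config$at_least_one[[s]], catalog$name)
    need_idx <- need_idx[p[need_idx] > 0]
    m <- draw_condition_matrix(n_g, p, need_idx)
    hit <- which(m, arr.ind = TRUE)
    per_row <- split(catalog$name[hit[, 2]], hit[, 1])
    conds[idx] <- replicate(n_g, character(), simplify = FALSE)
    conds[idx[as.integer(names(per_row))]] <- purrr::map(per_row, sort)

    u <- config$utilization_params[[s]]
    ed_n[idx] <- sample_count(n_g, u$ed[["mean"]], u$ed[["sd"]])
    soc_n[idx] <- sample_count(n_g, u$specialist[["mean"]],
                               u$specialist[["sd"]])
    adm_n[idx] <- sample_count(n_g, u$admissions[["mean"]],
                               u$admissions[["sd"]],
                               config$admission_constraint[[s]])
    died[idx] <- runif(n_g) < config$mortality_prob[[s]]
  }
  adm_n <- pmin(adm_n, 100L)  # keeps episode placement feasible in one year

  birth <- as.Date(sprintf("%d-01-01", iy - age)) -
    as.integer(floor(runif(n) * 365))
  death <- as.Date(rep(NA_character_, n))
  death[died] <- year_start + as.integer(floor(runif(sum(died)) * 365))
  patients <- tibble::tibble(
    patient_id = pid, birth_date = birth,
    gender = ifelse(male, "male", "female"), ethnicity = eth,
    death_date = death,
    terminal_flag = seg == config$terminal_flag_segment)

  diagnoses <- make_diagnoses(pid, conds, catalog, iy, config$lookback_years)
  encounters <- make_encounters(pid, ed_n, soc_n, adm_n, year_start)

  structure(list(patients = patients, diagnoses = diagnoses,
                 encounters = encounters,
                 truth = tibble::tibble(patient_id = pid,
                                        segment = segment_factor(seg))),
            class = "synthetic_cohort")
}

# One diagnosis record per (patient, condition): code drawn from the
# condition's patterns (ICD-10 0.55 / ICD-9 0.35 / primary-care 0.10, with
# fallback when a system has no patterns), half the ICD codes extended by a
# random trailing digit to exercise prefix matching, date uniform over the
# look-back window.
make_diagnoses <- function(pid, conds, catalog, index_year, lookback_years) {
  k <- lengths(conds)
  if (sum(k) == 0) {
    return(tibble::tibble(patient_id = character(), code = character(),
                          system = character(), date = as.Date(character())))
  }
  pairs <- tibble::tibble(patient_id = rep(pid, k),
                          condition = unlist(conds))
  row <- match(pairs$condition, catalog$name)
  u <- runif(nrow(pairs))
  want <- ifelse(u < 0.55, "icd10", ifelse(u < 0.90, "icd9", "primary_care"))
  avail <- cbind(icd10 = lengths(catalog$icd10)[row] > 0,
                 icd9 = lengths(catalog$icd9)[row] > 0,
                 primary_care = lengths(catalog$primary_care)[row] > 0)
  pick <- want
  no_want <- !avail[cbind(seq_along(pick), match(pick, colnames(avail)))]
  if (any(no_want)) {
    pick[no_want] <- apply(avail[no_want, , drop = FALSE], 1,
                           function(a) colnames(avail)[which(a)[1]])
  }
  code <- character(nrow(pairs))
  for (sys in catalog_systems()) {
    sel <- which(pick == sys)
    if (length(sel) == 0) next
    for (cn in unique(pairs$condition[sel])) {
      ssel <- sel[pairs$condition[sel] == cn]
      pats <- catalog[[sys]][[match(cn, catalog$name)]]
      code[ssel] <- pats[1 + as.integer(floor(runif(length(ssel)) *
                                                length(pats)))]
    }
  }
  extend <- pick != "primary_care" & runif(nrow(pairs)) < 0.5
  code[extend] <- paste0(code[extend],
                         as.integer(floor(runif(sum(extend)) * 10)))
  win_start <- as.Date(sprintf("%d-01-01", index_year - lookback_years + 1))
  win_days <- as.integer(as.Date(sprintf("%d-12-31", index_year)) -
                           win_start) + 1L
  tibble::tibble(patient_id = pairs$patient_id, code = code, system = pick,
                 date = win_start +
                   as.integer(floor(runif(nrow(pairs)) * win_days)))
}

make_encounters <- function(pid, ed_n, soc_n, adm_n, year_start) {
  single <- function(counts, modality) {
    total <- sum(counts)
    if (total == 0) {
      return(tibble::tibble(patient_id = character(), modality = character(),
                            start_date = as.Date(character()),
                            end_date = as.Date(character())))
    }
    tibble::tibble(patient_id = rep(pid, counts), modality = modality,
                   start_date = year_start +
                     as.integer(floor(runif(total) * 365)),
                   end_date = as.Date(rep(NA_character_, total)))
  }
  ed <- single(ed_n, "ED")
  soc <- single(soc_n, "specialist_clinic")

  # inpatient episodes: the year is split into k equal blocks per patient and
  # one short stay is placed in each block with a 2-day guard before the
  # block boundary, so merged-episode counting recovers k exactly
  ip <- NULL
  tot_adm <- sum(adm_n)
  if (tot_adm > 0) {
    has <- adm_n > 0
    k_rep <- rep(adm_n[has], adm_n[has])
    j <- sequence(adm_n[has])
    block <- 365L %/% k_rep
    los_max <- pmin(5L, block - 2L)
    los <- 1L + as.integer(floor(runif(tot_adm) * los_max))
    offset <- as.integer(floor(runif(tot_adm) * (block - los - 1L)))
    start_day <- (j - 1L) * block + offset
    ip <- tibble::tibble(patient_id = rep(pid[has], adm_n[has]),
                         modality = "inpatient",
                         start_date = year_start + start_day,
                         end_date = year_start + start_day + los - 1L)
  }

  enc <- dplyr::bind_rows(ed, soc, ip)
  covered <- unique(enc$patient_id)
  missing <- setdiff(pid, covered)
  if (length(missing) > 0) {
    pc <- tibble::tibble(patient_id = missing, modality = "primary_care",
                         start_date = year_start +
                           as.integer(floor(runif(length(missing)) * 365)),
                         end_date = as.Date(rep(NA_character_,
                                                length(missing))))
    enc <- dplyr::bind_rows(enc, pc)
  }
  dplyr::arrange(enc, .data$patient_id, .data$start_date, .data$modality)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d diagnoses, %d encounters\n",
              nrow(x$patients), nrow(x$diagnoses), nrow(x$encounters)))
  print(table(x$truth$segment))
  invisible(x)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n_patients = %d, seed = %d, index year %d\n",
              x$n_patients, x$seed, x$index_year))
  cat("segment proportions:\n")
  print(round(x$segment_proportions, 4))
  invisible(x)
}
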