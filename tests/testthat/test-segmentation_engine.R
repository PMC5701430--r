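test_that("eligibility requires adult age and an index-year encounter", {
  patients <- dplyr::bind_rows(
    pt("minor", birth_date = "1992-06-01"),          # 19 at 1 Jan 2012
    pt("no_visit", birth_date = "1962-01-01"),       # 50, visits in 2011 only
    pt("adult", birth_date = "1991-01-01"))          # exactly 21 at 1 Jan 2012
  encounters <- dplyr::bind_rows(
    enc("minor", start_date = "2012-03-01"),
    enc("minor", start_date = "2012-04-01"),
    enc("no_visit", start_date = "2011-06-01"),
    enc("adult", "primary_care", "2012-06-01"))
  expect_equal(filter_eligible(patients, encounters, default_cfg), "adult")
})

test_that("age is computed in completed years at 1 January of the index year", {
  # born 2 Jan 1991: 20 completed years at 1 Jan 2012
  p <- dplyr::bind_rows(pt("a", birth_date = "1991-01-02"),
                        pt("b", birth_date = "1991-01-01"))
  e <- dplyr::bind_rows(enc("a", start_date = "2012-02-01"),
                        enc("b", start_date = "2012-02-01"))
  expect_equal(filter_eligible(p, e, default_cfg), "b")
})

test_that("condition detection honours the five-calendar-year look-back", {
  inside <- dx("A", "I10", date = "2008-01-01")   # first day of the window
  outside <- dx("A", "I10", date = "2007-12-31")  # sixth prior year
  expect_equal(detect_conditions(inside, cat34, default_cfg), "hypertension")
  expect_length(detect_conditions(outside, cat34, default_cfg), 0)

  multi <- dplyr::bind_rows(dx("A", "I10", date = "2009-05-05"),
                            dx("A", "I10.9", date = "2011-05-05"),
                            dx("A", "E78.5", date = "2012-05-05"))
  expect_equal(detect_conditions(multi, cat34, default_cfg),
               c("hyperlipidemia", "hypertension"))
  expect_error(detect_conditions(dplyr::bind_rows(dx("A", "I10"),
                                                  dx("B", "I10")),
                                 cat34, default_cfg), "single patient")
})

test_that("admission counting merges overlapping and abutting episodes", {
  disjoint <- dplyr::bind_rows(inpatient("A", "2012-01-10", "2012-01-12"),
                               inpatient("A", "2012-05-01"),
                               inpatient("A", "2012-09-20", "2012-09-25"))
  expect_equal(count_admissions(disjoint, 2012), 3)

  overlapping <- dplyr::bind_rows(inpatient("A", "2012-03-01", "2012-03-10"),
                                  inpatient("A", "2012-03-05", "2012-03-12"))
  expect_equal(count_admissions(overlapping, 2012), 1)

  # transfer discharged one day, admitted the next: one episode
  abutting <- dplyr::bind_rows(inpatient("A", "2012-03-01", "2012-03-04"),
                               inpatient("A", "2012-03-05", "2012-03-06"))
  expect_equal(count_admissions(abutting, 2012), 1)

  gap2 <- dplyr::bind_rows(inpatient("A", "2012-03-01", "2012-03-04"),
                           inpatient("A", "2012-03-06"))
  expect_equal(count_admissions(gap2, 2012), 2)

  ed_only <- dplyr::bind_rows(enc("A", "ED", "2012-01-01"),
                              enc("A", "ED", "2012-02-01"),
                              enc("A", "ED", "2012-03-01"),
                              enc("A", "ED", "2012-04-01"))
  expect_equal(count_admissions(ed_only, 2012), 0)
  expect_equal(count_admissions(inpatient("A", "2011-06-01"), 2012), 0)
})

test_that("segment assignment follows the precedence hierarchy", {
  seg <- function(conds, adm, flag = FALSE) {
    assign_segment(conds, cat34, adm, default_cfg, terminal_flag = flag)
  }
  expect_equal(seg("metastatic_disease", 1)$segment, "end_of_life")
  expect_equal(seg(c("hypertension", "hyperlipidemia"), 0)$segment,
               "stable_chronic")
  expect_equal(seg(c("atrial_fibrillation", "hypertension"), 4)$segment,
               "complex_freq")
  expect_equal(seg(character(), 1)$segment, "serious_acute")
  expect_equal(seg(character(), 0)$segment, "mostly_healthy")
  # terminal designation without a terminal diagnosis also fires rule 1
  expect_equal(seg(c("hypertension"), 0, flag = TRUE)$segment, "end_of_life")
  # a stable-chronic patient with an admission is serious acute under the
  # default precedence
  expect_equal(seg("hypertension", 1)$segment, "serious_acute")
  expect_error(seg("not_a_condition", 0), "not in catalog")
})

test_that("the frequent-admitter threshold is sharp at 3", {
  thr <- default_cfg$frequent_admission_threshold
  below <- assign_segment("atrial_fibrillation", cat34, thr - 1, default_cfg)
  at <- assign_segment("atrial_fibrillation", cat34, thr, default_cfg)
  expect_equal(below$segment, "complex_no_freq")
  expect_equal(at$segment, "complex_freq")
})

test_that("segment_cohort composes the stages, one assignment per eligible patient", {
  patients <- pt(sprintf("p%d", 1:5), birth_date = "1960-01-01")
  diagnoses <- dplyr::bind_rows(
    dx("p1", "C78"),                      # metastatic
    dx("p2", "I10"), dx("p2", "E78"),     # stable only
    dx("p3", "I48"), dx("p3", "I10"))     # complex + stable
  encounters <- dplyr::bind_rows(
    inpatient("p1", "2012-01-10"),
    enc("p2", start_date = "2012-02-01"),
    inpatient("p3", "2012-01-05"), inpatient("p3", "2012-03-05"),
    inpatient("p3", "2012-05-05"), inpatient("p3", "2012-07-05"),
    inpatient("p4", "2012-04-01"),
    enc("p5", start_date = "2012-08-01"))
  asg <- segment_cohort(patients, diagnoses, encounters, cat34, default_cfg)
  expect_equal(nrow(asg), 5)
  got <- stats::setNames(as.character(asg$segment), asg$patient_id)
  expect_equal(got[c("p1", "p2", "p3", "p4", "p5")],
               c(p1 = "end_of_life", p2 = "stable_chronic",
                 p3 = "complex_freq", p4 = "serious_acute",
                 p5 = "mostly_healthy"))
  expect_equal(asg$index_year_admissions[asg$patient_id == "p3"], 4L)
  expect_setequal(asg$conditions_found[asg$patient_id == "p3"][[1]],
                  c("atrial_fibrillation", "hypertension"))

  empty <- segment_cohort(empty_patients(), empty_dx(), empty_enc(),
                          cat34, default_cfg)
  expect_equal(nrow(empty), 0)
})

test_that("every eligible patient gets exactly one segment (partition property)", {
  cohort <- generate_cohort(default_generator_config(2000, seed = 11))
  asg <- segment_cohort(cohort$patients, cohort$diagnoses, cohort$encounters,
                        cat34, default_cfg)
  expect_equal(nrow(asg), 2000)
  expect_equal(anyDuplicated(asg$patient_id), 0)
  expect_false(any(is.na(asg$segment)))
  expect_equal(sum(table(asg$segment)), 2000)
})

test_that("adding admissions never demotes a patient (monotonicity property)", {
  precedence_rank <- stats::setNames(seq_along(default_cfg$precedence),
                                     default_cfg$precedence)
  set.seed(404)
  cond_pool <- cat34$name
  for (i in 1:60) {
    conds <- sample(cond_pool, sample(0:3, 1))
    adm <- sample(0:4, 1)
    flag <- runif(1) < 0.1
    before <- assign_segment(conds, cat34, adm, default_cfg, flag)$segment
    after <- assign_segment(conds, cat34, adm + 1, default_cfg, flag)$segment
    expect_lte(precedence_rank[[after]], precedence_rank[[before]])
  }
})

test_that("custom thresholds and ED-inclusive acute rule are honoured", {
  cfg5 <- segmentation_config(frequent_admission_threshold = 5)
  expect_equal(assign_segment("atrial_fibrillation", cat34, 4, cfg5)$segment,
               "complex_no_freq")
  cfg_ed <- segmentation_config(serious_acute_includes_ed = TRUE)
  expect_equal(assign_segment(character(), cat34, 0, cfg_ed,
                              ed_visits = 2)$segment, "serious_acute")
  expect_error(segmentation_config(precedence = c("end_of_life")),
               "permutation")
  expect_error(segmentation_config(lookback_years = 0), "lookback_years")
})
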