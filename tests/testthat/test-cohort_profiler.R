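test_that("rate_from_counts reproduces printed number-(%) cells", {
  expect_equal(rate_from_counts(769, 4705, 0), 16)
  expect_equal(rate_from_counts(982, 2955, 0), 33)
  expect_equal(rate_from_counts(2540, 4705, 1), 54.0)
  expect_equal(rate_from_counts(0, 100, 1), 0.0)
  # half away from zero, not banker's rounding
  expect_equal(rate_from_counts(5, 1000, 0), 1)
  expect_equal(rate_from_counts(15, 1000, 0), 2)
  expect_error(rate_from_counts(1, 0), "positive")
  expect_error(rate_from_counts(5, 4), "numerator")
})

test_that("rate_from_counts is monotone in the numerator", {
  den <- 997
  rates <- rate_from_counts(0:den, den, 1)
  expect_true(all(diff(rates) >= 0))
})

test_that("chi-square matches the Pearson formula (small-table oracle)", {
  pearson_oracle <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    list(statistic = sum((m - e)^2 / e),
         df = (nrow(m) - 1) * (ncol(m) - 1))
  }
  hom <- chi_square_test(matrix(5, 2, 2))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$df, 1)
  expect_equal(hom$p_value, 1)

  diag2 <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag2$statistic, 20)
  expect_equal(diag2$df, 1)

  expect_equal(chi_square_test(matrix(1, 2, 3))$df, 2)

  set.seed(31)
  for (i in 1:50) {
    r <- sample(2:3, 1); c <- sample(2:3, 1)
    m <- matrix(sample(0:10, r * c, replace = TRUE), r, c)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    got <- chi_square_test(m)
    want <- pearson_oracle(m)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value,
                 stats::pchisq(want$statistic, want$df, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(chi_square_test(matrix(c(1, 1, 0, 0), 2)), "degenerate")
  expect_error(chi_square_test(matrix(1, 1, 2)), "at least 2x2")
})

test_that("one-way ANOVA matches hand computation and the t-squared identity", {
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)

  hand <- one_way_anova(list(c(0, 2), c(2, 4)))
  expect_equal(hand$statistic, 2.0)   # SS_between = 4, SS_within = 4
  expect_equal(hand$df, c(1, 2))

  degenerate <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(degenerate$statistic, Inf)
  expect_equal(degenerate$p_value, 0)
  flat <- one_way_anova(list(c(3, 3), c(3, 3)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  set.seed(17)
  for (i in 1:25) {
    g1 <- rnorm(sample(3:9, 1)); g2 <- rnorm(sample(3:9, 1))
    f <- one_way_anova(list(g1, g2))
    t <- stats::t.test(g1, g2, var.equal = TRUE)
    expect_equal(f$statistic, unname(t$statistic)^2, tolerance = 1e-10)
    expect_equal(f$p_value, t$p.value, tolerance = 1e-10)
  }
  expect_error(one_way_anova(list(1:3)), "two groups")
  expect_error(one_way_anova(list(numeric(), 1:3)), "at least one value")
})

make_hand_cohort <- function() {
  patients <- dplyr::bind_rows(
    pt(sprintf("h%d", 1:6), birth_date = "1950-01-01", gender = "male"),
    pt(sprintf("h%d", 7:10), birth_date = "1980-01-01", gender = "female",
       ethnicity = "malay"))
  patients$death_date[patients$patient_id == "h1"] <- as.Date("2012-11-01")
  encounters <- dplyr::bind_rows(
    enc(sprintf("h%d", 1:10), start_date = "2012-03-03"),
    inpatient("h1", "2012-02-01"), inpatient("h1", "2012-06-01"),
    inpatient("h1", "2012-09-01"),
    enc("h2", "ED", "2012-04-04"),
    enc("h3", "specialist_clinic", "2012-05-05"))
  diagnoses <- dplyr::bind_rows(
    dx("h1", "I48"), dx("h1", "I10"),
    dx("h2", "I10"), dx("h3", "I10"), dx("h4", "E78"))
  asg <- segment_cohort(patients, diagnoses, encounters, cat34, default_cfg)
  list(patients = patients, encounters = encounters, asg = asg)
}

test_that("profile_segments matches a hand-counted fixture", {
  h <- make_hand_cohort()
  prof <- profile_segments(h$asg, h$patients, h$encounters, cat34,
                           default_cfg)
  n_by_seg <- stats::setNames(prof$segments$n, prof$segments$segment)
  expect_equal(n_by_seg[["complex_freq"]], 1)      # h1: AF + 3 admissions
  expect_equal(n_by_seg[["stable_chronic"]], 3)    # h2, h3, h4
  expect_equal(n_by_seg[["mostly_healthy"]], 6)
  expect_equal(sum(prof$segments$n), 10)
  expect_equal(prof$segments$percent[prof$segments$segment ==
                                       "mostly_healthy"], 60.0)

  mort <- prof$utilization[prof$utilization$variable == "mortality", ]
  expect_equal(mort$count[mort$segment == "complex_freq"], 1L)
  expect_equal(mort$percent[mort$segment == "complex_freq"], 100.0)

  adm <- prof$utilization[prof$utilization$variable == "admissions", ]
  expect_equal(adm$mean[adm$segment == "complex_freq"], 3)
  expect_equal(adm$mean[adm$segment == "mostly_healthy"], 0)

  prev <- prof$prevalence
  htn_sc <- prev[prev$condition == "hypertension" &
                   prev$segment == "stable_chronic", ]
  expect_equal(htn_sc$count, 2L)                   # h2, h3
  expect_equal(htn_sc$percent, 66.7)
  # conservation: prevalence counts never exceed the segment size
  expect_true(all(prev$count <= prev$segment_n))

  expect_error(profile_segments(h$asg, h$patients[-1, ], h$encounters,
                                cat34, default_cfg), "unknown patient")
})

test_that("a single-segment cohort profiles as 100% of one row", {
  patients <- pt(c("a", "b"), birth_date = "1960-01-01")
  encounters <- enc(c("a", "b"), start_date = "2012-01-15")
  asg <- segment_cohort(patients, empty_dx(), encounters, cat34, default_cfg)
  prof <- profile_segments(asg, patients, encounters, cat34, default_cfg)
  expect_equal(prof$segments$percent[prof$segments$segment ==
                                       "mostly_healthy"], 100.0)
  expect_equal(sum(prof$segments$n > 0), 1)
})

test_that("recovery_report counts agreement and disagreement", {
  truth <- tibble::tibble(patient_id = sprintf("p%d", 1:10),
                          segment = rep(c("mostly_healthy", "stable_chronic"),
                                        each = 5))
  same <- truth
  rep1 <- recovery_report(truth, same)
  expect_equal(rep1$accuracy, 1.0)
  expect_equal(sum(rep1$confusion) - sum(diag(rep1$confusion)), 0)

  flipped <- truth
  flipped$segment[1] <- "serious_acute"
  expect_equal(recovery_report(truth, flipped)$accuracy, 0.9)

  other <- truth
  other$patient_id <- sprintf("q%d", 1:10)
  expect_error(recovery_report(truth, other), "same patient ids")
})
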