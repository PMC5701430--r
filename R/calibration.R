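# Reference calibration: published per-segment descriptive statistics of a
# 825,874-patient Singapore regional-health-system cohort (index year 2012)
# that the synthetic generator emulates.  Counts are stored rather than
# rounded percentages so derived proportions are exact.

seg_keys <- function() segment_levels()

reference_calibration <- function() {
  segs <- seg_keys()
  named <- function(x) stats::setNames(x, segs)

  segment_counts <- named(c(506101, 44023, 177550, 90540, 4705, 2955))

  # age-group counts (21-39 / 40-64 / 65-84 / >=85) per segment
  age_counts <- matrix(c(
    217648, 230499, 54890, 3064,   # mostly_healthy
    23898,  15011,  4646,  468,    # serious_acute
    10873,  92032,  68607, 6038,   # stable_chronic
    8217,   43387,  35063, 3873,   # complex_no_freq
    279,    1955,   2157,  314,    # complex_freq
    180,    1712,   991,   72),    # end_of_life
    nrow = 4, dimnames = list(c("21-39", "40-64", "65-84", "85+"), segs))

  male_counts <- named(c(209969, 12620, 79196, 42186, 2447, 1286))

  ethnicity_counts <- matrix(c(
    346461, 45406, 50589, 63645,
    25617,  5121,  7022,  6263,
    137299, 12286, 21226, 6739,
    69173,  7248,  9152,  4967,
    3415,   469,   614,   207,
    2324,   127,   239,   265),
    nrow = 4, dimnames = list(c("chinese", "indian", "malay", "other"), segs))

  # index-year utilization per patient: mean and SD per segment
  util <- list(
    ed_visits = list(mean = named(c(0.11, 0.56, 0.05, 0.44, 3.21, 0.96)),
                     sd   = named(c(0.38, 0.95, 0.31, 0.94, 3.16, 1.36))),
    specialist_visits = list(
      mean = named(c(2.42, 8.20, 2.04, 8.52, 24.30, 27.48)),
      sd   = named(c(3.67, 7.25, 4.34, 11.09, 19.54, 23.68))),
    admissions = list(mean = named(c(0, 1.18, 0, 0.44, 4.33, 1.50)),
                      sd   = named(c(0, 0.51, 0, 0.72, 2.12, 1.63))))

  mortality_counts <- named(c(666, 266, 286, 2903, 769, 982))

  # chronic-disease prevalence counts for the four chronic segments
  # (columns: stable_chronic, complex_no_freq, complex_freq, end_of_life)
  prev <- rbind(
    diabetes_uncomplicated       = c(30823, 23506, 1622, 178),
    hypertension                 = c(62413, 39054, 2540, 433),
    ckd_without_esrf             = c(4954, 6674, 1341, 42),
    asthma                       = c(7041, 3697, 246, 34),
    hyperlipidemia               = c(59426, 34951, 1885, 219),
    osteoarthritis               = c(22367, 10966, 619, 98),
    osteoporosis                 = c(452, 208, 2, 2),
    benign_prostatic_hypertrophy = c(1265, 687, 28, 3),
    copd_without_cor_pulmonale   = c(3084, 4154, 453, 72),
    hyperthyroidism              = c(1720, 422, 14, 2),
    hypothyroidism               = c(2915, 1076, 45, 1),
    diabetes_with_complications  = c(0, 8935, 450, 12),
    stroke                       = c(4737, 8207, 680, 67),
    ckd5_or_esrf                 = c(950, 3600, 1241, 40),
    copd_with_cor_pulmonale      = c(2169, 3763, 441, 72),
    major_depression             = c(1302, 5398, 212, 22),
    schizophrenia                = c(273, 959, 50, 7),
    dementia                     = c(331, 671, 65, 4),
    bipolar_disorder             = c(2, 7, 0, 0),
    collagen_vascular_disease    = c(107, 1412, 128, 15),
    anxiety                      = c(693, 2616, 53, 6),
    parkinsons_disease           = c(282, 841, 62, 7),
    epilepsy                     = c(289, 1801, 108, 16),
    coronary_heart_disease       = c(10159, 19562, 1513, 122),
    atrial_fibrillation          = c(0, 718, 91, 2),
    hip_fracture                 = c(20, 12, 2, 0),
    spine_fracture               = c(185, 827, 77, 8),
    liver_disease_moderate_severe = c(0, 2843, 245, 34),
    malignancy_non_metastatic    = c(0, 25630, 885, 1915),
    thromboembolism              = c(0, 42, 12, 3),
    pressure_ulcer               = c(10, 166, 29, 2),
    heart_failure                = c(936, 4880, 811, 40),
    peripheral_vascular_disease  = c(655, 3223, 372, 25),
    metastatic_disease           = c(6, 181, 16, 1151))
  colnames(prev) <- segs[3:6]

  # published per-segment mean number of chronic conditions
  mean_conditions <- stats::setNames(c(2.4, 2.4, 3.5, 1.6), segs[3:6])

  list(segment_counts = segment_counts,
       cohort_total = sum(segment_counts),
       age_counts = age_counts,
       male_counts = male_counts,
       ethnicity_counts = ethnicity_counts,
       utilization = util,
       mortality_counts = mortality_counts,
       prevalence_counts = prev,
       mean_conditions = mean_conditions)
}

#' Published per-segment cohort counts
#'
#' The reference segment sizes of the 2012 regional-health-system cohort the
#' generator is calibrated to, as a named integer vector with attribute
#' `cohort_total` (825,874).
#'
#' @return Named numeric vector of six segment counts.
#' @examples
#' sum(segment_reference_counts())
#' @export
segment_reference_counts <- function() {
  cal <- reference_calibration()
  structure(cal$segment_counts, cohort_total = cal$cohort_total)
}
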