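Package: popsegment
Title: Expert-Defined Patient Population Segmentation from Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments an adult health-system population into six mutually
    exclusive needs-based segments (mostly healthy, serious acute illness,
    stable chronic, complex chronic with and without frequent hospital
    admissions, and end of life) from routine electronic health record
    extracts.  Chronic conditions are detected by mapping ICD-9, ICD-10 and
    primary-care codes against a 34-condition catalog over a five-calendar-year
    look-back window; frequent hospital admission is defined as three or more
    merged inpatient episodes in the index year.  Includes a calibrated
    synthetic-cohort generator with known truth segments for end-to-end
    validation, and a profiler that produces per-segment demographic,
    utilization, mortality and condition-prevalence tables with chi-square and
    one-way ANOVA comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
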