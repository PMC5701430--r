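# popsegment

Rule-based segmentation of an adult health-system population into six
mutually exclusive, needs-based segments from routine electronic health
record extracts — for health-services researchers and population-health
analysts who need a practical, reproducible "first cut" of a regional
population for integrated-care and resource planning.

## The framework

Every adult (≥ 21 completed years at 1 January of an index year) with at
least one encounter in that year is classified by the first matching rule in
a precedence hierarchy:

| # | Rule | Segment |
|---|------|---------|
| 1 | any terminal condition (or terminal flag) | End of life |
| 2 | any complex condition **and** ≥ 3 index-year admissions | Complex chronic, frequent admissions |
| 3 | any complex condition | Complex chronic, no frequent admissions |
| 4 | ≥ 1 index-year admission | Serious acute illness but curable |
| 5 | any stable condition | Stable chronic |
| 6 | otherwise | Mostly healthy |

Chronic conditions are detected over a 5-calendar-year look-back by mapping
ICD-9/ICD-10 codes (normalized, prefix-matched) and primary-care labels
against a shipped 34-condition catalog (CDMP roster plus Charlson/Elixhauser
comorbidities, Quan et al. code mappings).  "Frequent hospital admissions"
means ≥ 3 inpatient episodes in the index year after merging overlapping or
same-day-contiguous stays.  Every threshold, the precedence order and the
catalog (including each condition's stable/complex/terminal class) are
configurable.

Because no patient-level data can ship with the package, it includes a
synthetic-EHR generator calibrated to the published per-segment tables of a
~826k-patient regional cohort (segment shares, demographics, utilization
moments, mortality, condition prevalence), with known truth segments: every
generated patient satisfies exactly their truth segment's rule, so the
segmenter must recover 100% of labels — the pipeline's built-in oracle.

## Worked example

```r
library(popsegment)

cohort <- generate_cohort(default_generator_config(20000, seed = 42))
asg <- segment_cohort(cohort$patients, cohort$diagnoses, cohort$encounters,
                      default_catalog(), segmentation_config())
prof <- profile_segments(asg, cohort$patients, cohort$encounters,
                         default_catalog(), segmentation_config())
prof$segments
#> # A tibble: 6 × 3
#>   segment             n percent
#>   <chr>           <int>   <dbl>
#> 1 mostly_healthy  12269    61.3
#> 2 serious_acute    1026     5.1
#> 3 stable_chronic   4325    21.6
#> 4 complex_no_freq  2181    10.9
#> 5 complex_freq      119     0.6
#> 6 end_of_life        80     0.4
```

The shares match the published cohort (61.3 / 5.3 / 21.5 / 11.0 / 0.6 /
0.4%) up to sampling noise at n = 20,000.  Truth recovery is exact:

```r
recovery_report(cohort$truth, asg)
#> <recovery_report> 20000 patients, accuracy 1.0000
```

and per-segment utilization reproduces the calibrated moments, e.g. mean
(SD) index-year admissions:

```r
subset(prof$utilization, variable == "admissions")[, c("segment", "mean", "sd")]
#>           segment  mean    sd
#>    mostly_healthy 0.000 0.000
#>     serious_acute 1.187 0.509
#>    stable_chronic 0.000 0.000
#>   complex_no_freq 0.372 0.585
#>      complex_freq 4.210 2.633
#>       end_of_life 1.288 1.265
```

(the frequent-admitter target is 4.33 ± 2.12; with only 119 such patients
at this n the mean is within sampling error).  Real extracts are consumed
with `read_patients()` / `read_diagnoses()` / `read_encounters()` and the
same `segment_cohort()` call; a shell entry point with `generate`,
`segment`, `profile` and `validate` subcommands ships at
`inst/scripts/popsegment`.

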