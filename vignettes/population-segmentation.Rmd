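---
title: "Six-segment population segmentation from EHR extracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Six-segment population segmentation from EHR extracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsegment)
```

## The segmentation model

`popsegment` implements an expert-defined, rule-based segmentation of an
adult health-system population into six mutually exclusive segments, driven
entirely by variables that routine EHR and administrative extracts carry:
diagnosis codes, encounter dates and modalities, and death dates.

The cohort is every patient aged ≥ 21 completed years at 1 January of an
*index year* with at least one encounter (inpatient, emergency department,
specialist outpatient clinic, or primary care) starting in that year.
Chronic conditions are detected by scanning all diagnosis codes dated within
a five-calendar-year *look-back window* ending with the index year against a
34-condition catalog; each condition carries a class:

* **stable** — chronic disease compatible with routine primary-care
  management (hypertension, hyperlipidemia, uncomplicated diabetes, …);
* **complex** — disease that marks a complex chronic patient (diabetes with
  chronic complications, non-metastatic malignancy, atrial fibrillation,
  moderate/severe liver disease, thromboembolism);
* **terminal** — markers of terminal illness (metastatic disease).

Assignment applies the first matching rule in precedence order:

1. any terminal condition, or a per-patient terminal designation → **end of
   life**;
2. any complex condition and ≥ 3 merged inpatient episodes in the index
   year → **complex chronic with frequent hospital admissions**;
3. any complex condition → **complex chronic without frequent hospital
   admissions**;
4. ≥ 1 index-year admission → **serious acute illness but curable**;
5. any stable condition → **stable chronic**;
6. otherwise → **mostly healthy**.

Because the rules are a precedence hierarchy, every eligible patient
receives exactly one segment (the partition property), and adding an
admission can only move a patient toward a higher-precedence segment
(monotonicity).  Both properties are exercised in the test suite.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `index_year` | 2012 | calendar year | fixes cohort, utilization window, mortality window |
| `lookback_years` | 5 | years, inclusive of index year | diagnosis-code scan; long window absorbs coding lapses |
| `frequent_admission_threshold` | 3 | admissions/year | frequent-admitter cut, a standard high-utilizer proxy |
| `min_age` | 21 | completed years at 1 Jan | adult population definition |
| `precedence` | rules 1–6 above | — | tie-breaking between overlapping definitions |

Three choices here were genuinely open and are worth recording:

* **Precedence order.** The source tables report zero index-year admissions
  for both the mostly-healthy and stable-chronic segments, which is only
  possible if every admitted patient without complex disease lands in the
  serious-acute segment — i.e. the admission rule outranks the
  stable-condition rule.  We adopt that order and expose it as
  configuration.
* **Frequent-admission window.** The reference tables show the
  frequent-admitter segment with mean 1.71 admissions in the *prior* year
  but 4.33 (all ≥ 3) in the index year; only an index-year counting window
  is consistent with both, so the threshold is applied to index-year
  admissions.
* **Serious-acute trigger.** Whether an ED-only patient can be serious
  acute is unstated in the source framework; the default requires an
  admission, and `serious_acute_includes_ed = TRUE` switches the rule to
  admission-or-ED.

Two further numerical conventions: dates are ISO 8601 and age is computed in
completed years at 1 January of the index year, making eligibility
deterministic; and inpatient records that overlap or abut within one day
(`next start ≤ previous end + 1`) are merged into a single episode before
counting, so that inter-hospital transfers do not double-count as
readmissions.

## The condition catalog

The shipped catalog holds 34 conditions — the Singapore Chronic Disease
Management Program core roster extended with Charlson/Elixhauser
comorbidities — with ICD-9 and ICD-10 prefixes adapted from the published
Quan et al. administrative-code mappings and case-folded verbatim labels for
primary-care coding schemes.  Codes are normalized (uppercase, periods
stripped) and matched by prefix, so dotted and undotted ICD dialects behave
identically.  The pattern sets are mutually disjoint under prefix extension
— a property the tests verify exhaustively — so every code resolves to at
most one condition.

The stable/complex split cannot be fully recovered from the published main
text; we derive it from the observation that six conditions show exactly
0.0% prevalence in the stable-chronic segment (they are definitionally
excluded from it) and treat metastatic disease as the terminal marker.
Intuitively severe conditions with small but nonzero stable-segment
prevalence (end-stage renal failure, heart failure, stroke) therefore
default to *stable*; the JSON catalog makes every category user-overridable
precisely because this heuristic is imperfect.  Likewise, the end-of-life
segment in the source shows only 39% metastatic disease, so terminal
diagnosis codes alone cannot reproduce its membership; the patients table
accepts an optional `terminal_flag` column as an additional end-of-life
trigger.

## The synthetic-cohort generator

No patient-level data are distributable, so the package ships a generator
(`generate_cohort()`) calibrated to the published per-segment tables:
segment proportions from the exact segment counts (506,101 / 44,023 /
177,550 / 90,540 / 4,705 / 2,955 of 825,874); per-segment age-group, gender
and ethnicity multinomials; per-segment index-year ED, specialist-clinic and
admission count distributions (given mean and SD); per-segment mortality;
and a per-segment condition-prevalence matrix.

Design decisions, in the package's own terms:

* **Counts.** Utilization counts are drawn from a negative binomial fitted
  by method of moments (`size = μ²/(σ²−μ)`), falling back to Poisson when
  the variance does not exceed the mean — most published cells are
  overdispersed.  Structural constraints follow each segment's defining
  rule: zero admissions (mostly healthy, stable chronic), at least one
  (serious acute; drawn as 1 + a moment-matched residual so the target
  moments are preserved), at most threshold−1 (complex without frequent
  admissions, by rejection), at least threshold (frequent admitters, again
  by shifting).  Inpatient episodes are placed in equal blocks of the year
  with a two-day guard so episode merging provably recovers the drawn
  count.
* **Conditions.** Condition sets are independent Bernoulli draws per
  condition given the segment.  Segments that *require* a condition class
  (stable chronic requires a stable condition; the complex segments require
  a complex condition) are drawn conditionally on at least one success by
  rejection.  For the stable-chronic segment the published marginals sum to
  more than one, so a scaling factor with `1 − ∏(1 − p·t) = t` exists and
  the conditional marginals reproduce the published prevalences *exactly*.
  For the complex segments the published complex-condition prevalences sum
  to 0.358, which is incompatible with every member carrying at least one
  complex condition (the conditional marginals must sum to ≥ 1); this is an
  internal inconsistency of the source tables that no generator can
  resolve.  We keep the published values as sampling probabilities (the
  conditional marginals are inflated by 1/P(≥1) ≈ 3×) and rescale the
  stable-condition prevalences in those two segments by a factor derived at
  configuration-build time so the *expected condition count* equals the
  published per-segment mean (2.4 and 3.5).  `expected_prevalence()`
  exposes the implied marginals the empirical cohort should be compared to.
* **End of life.** All end-of-life patients carry the terminal flag, and the
  published end-of-life prevalence column is used verbatim (39% metastatic);
  metastatic prevalence is zeroed in the other segments (published values
  0.0–0.3%) so truth recovery is exact.
* **Ages and dates.** Age group is multinomial per segment, age uniform
  within group (≥ 85 capped at 100), birth dates placed so the reference-day
  age is exact.  Diagnosis dates are uniform over the look-back window, one
  record per condition.  Death dates are uniform over the index year.
* **Determinism.** All randomness flows from a single seed;
  `(seed, n_patients)` fixes the cohort byte-for-byte.

By construction every generated patient satisfies their truth segment's rule
and no higher-precedence rule, so `segment_cohort()` recovers the truth
labels with probability 1 — the pipeline's primary correctness oracle,
checked at n = 200,000 in the acceptance tests.

### What the generator does and does not emulate

It reproduces segment shares, segment-conditional demographics, index-year
utilization moments, mortality, and (where consistent) condition
prevalence.  It does **not** model correlation between conditions beyond
segment membership (so the stable-chronic mean condition count is the sum of
its prevalences, ≈ 1.24, not the published 2.4 — those two published numbers
are mutually inconsistent under any independence model), multi-year disease
progression, prior-year utilization, encounter/death ordering, or
household/geographic structure.  Passing round-trip and calibration tests
therefore demonstrates the correctness of the pipeline's logic on data with
the published marginal structure, not performance on real, messier EHR
streams (coding errors, cross-system utilization, incomplete death capture).

## Profiling and inference

`profile_segments()` rebuilds the published output surface: per-segment n
and share, age-group/gender/ethnicity counts with percentages, index-year
utilization means (SD), mortality counts and rates, mean condition counts,
and the full segment-by-condition prevalence table.  Percentages use
half-away-from-zero rounding at the per-table decimal conventions, which
reproduces printed cells bit-for-bit (`rate_from_counts(769, 4705, 0)` is
16).  Chi-square tests (Pearson, no continuity correction) compare
categorical rows across segments and one-way ANOVA the utilization counts;
p-values below 0.001 are rendered `<0.001` in formatted output but stored at
full precision.  Degenerate ANOVA inputs are handled explicitly: zero
within-group variance with distinct means reports an infinite statistic with
p = 0, and fully constant data reports 0 with p = 1.

## Problem sizes and verification

The test suite validates each operation against hand-computed or brute-force
oracles (Pearson formula evaluation on exhaustive small tables, the F = t²
identity, hand-counted ten-patient fixtures) and the end-to-end pipeline by
truth recovery at n = 1,000–200,000.  Calibration checks compare empirical
per-segment means against configured values within three Monte-Carlo
standard errors at n = 200,000, the scale at which the frequent-admitter
segment (~0.6% of patients) still has ≈ 1,200 members.  A full
generate-segment-profile cycle at that scale runs in well under a minute on
one core.

## Known limitations

* The stable/complex classification is a documented heuristic, not the
  source framework's (unpublished) expert table; users with their own expert
  classification should override categories in the catalog file.
* End-of-life detection beyond metastatic codes depends on the
  `terminal_flag` input column; real deployments would map palliative-care
  markers into it.
* Prior-year ("past utilization") columns are reported by the profiler only
  if the input encounters actually cover that year; the generator does not
  synthesize them.
* The generator's independence assumptions understate comorbidity
  clustering; condition-count distributions in the chronic segments are
  narrower than real ones.
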