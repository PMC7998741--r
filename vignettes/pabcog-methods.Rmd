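---
title: "Methods: posture-event processing, executive-function scoring, and group comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture-event processing, executive-function scoring, and group comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pabcog)
```

# Scope

`pabcog` implements the computation chain of an observational study design
common in physical-activity epidemiology: thigh-worn posture-event
accelerometry (ActivPAL-style event exports) is reduced to daily
physical-activity-behavior (PAB) summaries per participant; executive
functioning is scored from trial-level cognitive test exports; and the two
are compared across groups (here: vocational-education tracks) with
covariate-adjusted models. Because cohort-level event data of this kind are
rarely public, the package ships a synthetic-data module that generates
posture event streams and cognitive sessions with known ground truth, so
every downstream stage can be validated by parameter recovery rather than
by fixture files.

# The posture-event model

The native resolution of the input is the *event*: one contiguous episode
of a single activity class — `sitting` (sedentary time), `standing`,
`stepping`, or `time_in_bed` — with a start timestamp, a duration in
seconds, and a step count (zero for non-stepping classes). A valid stream
is sorted, gapless and non-overlapping. All processing derives from events:

* **Day splitting.** Events crossing local midnight are cut at the
  boundary; durations and step counts are apportioned pro rata, which
  preserves cadence. Midnight is defined by a fixed UTC offset per stream
  (daylight-saving transitions within a wear week are not modelled).
* **Completeness and validity.** A day is *complete* when the full 24 h
  are covered (0.5 s slack absorbs timestamp rounding through text files).
  A participant is *valid* with at least two complete weekdays and two
  complete weekend days (Saturday/Sunday); invalid participants are kept in
  the output with `valid = FALSE` so attrition is auditable, and are
  excluded from group analyses.
* **Sedentary bouts and the SB-ratio.** A bout is a maximal run of
  consecutive sitting events; standing, stepping and time in bed all
  terminate it. Time in bed is its own outcome class, never sedentary
  time. Midnight does *not* break a bout for length purposes, but a bout's
  time is attributed to the day(s) it occupies. The SB-ratio is the
  proportion of sedentary time accrued in bouts shorter than 30 min; a
  bout of exactly 30 min counts as prolonged (the strict reading of
  "shorter than"). The ratio is pooled over a participant's complete days
  (total short-bout sitting divided by total sitting); per-day averaging is
  available via `sb_ratio_method = "per_day"`. Zero sedentary time yields
  `NA`, never 0.
* **MVPA.** Moderate-to-vigorous physical activity is stepping time at
  cadence at or above 100 steps/min (the conventional 3-MET walking
  cadence), judged per stepping event — events are the native resolution
  of the format, and no sub-event cadence information exists. The
  threshold is a parameter (`cadence_threshold`).
* **Guideline adherence.** Youth rule: at least 60 min of MVPA on *every*
  complete measured day (partial first/last days are ignored — a daily
  minimum on a half-recorded day would fail mechanically). Adult rule:
  mean daily MVPA over complete days, times seven, reaching 150 min/week.

# The synthetic event generator

`generate_event_stream()` emulates a wear week as an alternating-state
renewal process:

* **Nights.** One in-bed episode per night, starting 23:00 ± 30 min
  (uniform jitter) with duration equal to the profile's `time_in_bed`
  target plus Gaussian noise (SD 15 min). The stream opens mid-night and
  closes at the end of the last day, so it spans exactly `n_days` × 24 h.
* **Waking episodes.** Sitting/standing/stepping episodes have exponential
  dwell times with class-specific means (`mean_bout_minutes`); episode
  classes are drawn with probability proportional to the renewal rate
  (daily-hours target divided by mean dwell), which makes long-run time
  shares proportional to the targets. The *first* episode of each waking
  interval is drawn by time share instead — the time-stationary start for
  a semi-Markov process with memoryless dwells — so the expected time per
  class in any finite window is exactly proportional, not just
  asymptotically. Unit tests verify convergence of recovered daily means
  to the targets within 3 standard errors over 200 simulated participants.
* **Cadence.** Each stepping episode is at MVPA cadence with probability
  `mvpa_fraction_of_stepping` (truncated normal around 115 steps/min) and
  below it otherwise (around 70 steps/min); step counts are integerized
  with a one-step margin so the 100 steps/min classification is stable
  under timestamp rounding. Because the Bernoulli draw is independent of
  episode length, the expected *time* fraction of stepping at MVPA cadence
  equals the profile parameter.

The default track profiles use the published covariate-adjusted daily-hour
group means of the four vocational tracks as generating targets, and the
published demographic table for covariate distributions. Adjusted means
need not close the 24-h day exactly; the residual (at most 0.01 h) is
absorbed into time in bed. Mean bout durations and MVPA fractions are free
parameters — the source study reports neither bout-length distributions
nor cadence mixtures — chosen once so that tracks differ in bout structure
(short, frequently interrupted sitting for Sports students; prolonged
sitting for Admin students) and so that youth-guideline adherence is
plausible (high only in the Sports track, with weekly adult adherence
essentially universal).

What the generator deliberately does **not** emulate: non-wear and
compliance gaps (streams are complete by construction), daytime napping as
a separate class, between-participant heterogeneity of daily targets
within a track, or heavy-tailed bout-length distributions. Two practical
consequences: synthetic cohorts are more homogeneous than real ones, so
group-comparison F statistics on synthetic data run larger than published
cohort values; and exponential bouts put less mass on very long sitting
spells than real behavior, so synthetic SB-ratios sit below the published
cohort's level (about 0.2–0.45 across tracks rather than 0.45–0.6) while
preserving the between-track ordering. Passing recovery tests therefore
demonstrates correctness of the processing chain, not realism of every
marginal distribution.

# Cognitive test scoring

## Letter-memory test (updating)

Twelve test trials of consonant series (lengths 5/7/9, each four times;
the 20-consonant alphabet excludes vowels and Y). The score is the total
number of correctly recalled letters over trials, regardless of order,
computed as a multiset intersection between the up-to-three recalled
entries and the three target letters — a duplicated target letter must be
recalled twice to count twice, and only order-insensitivity is granted.
`"Blank"` placeholders and missing entries score zero; trials with no
response at all contribute zero and are logged. The maximum is 36.

## Color-shape test (shifting and inhibition)

Five rounds of 16 practice plus 64 test trials: single-task shape and
color baselines (rounds 1–2), a randomly mixed shifting round (3), and two
bivalent inhibition rounds (4–5). The filter chain runs in this order:

1. **Chance performance** — any round with 32 or fewer correct of the 64
   test trials excludes the whole participant (practice trials are
   ignored; the criterion is about the 64 test trials).
2. **Non-shift trials** of round 3 (task repeats, and the round's first
   trial, which has no predecessor and hence no switch demand) are
   dropped.
3. **Congruent trials** of rounds 4–5 are dropped — stimuli in agreement
   require no inhibition.
4. **Reaction-time window**: RTs below 170 ms or above 5000 ms are
   dropped. The inequalities are strict: 170 ms and 5000 ms exactly are
   retained, and both boundaries are unit-tested.
5. **Incorrect trials** are dropped, so all RT statistics use correct
   trials only. This rule is applied *before* the outlier filter so that
   outlier statistics are computed on correct trials.
6. **Intrapersonal outliers**: per participant and per round, trials
   outside the mean ± 3 SD of the remaining trials are dropped in a
   single pass (no iteration to convergence — the filter removes "only
   this trial", not a recursively shrinking set). Pooled-across-rounds
   statistics are available via `sd_scope = "pooled"`.

Every removal is attributed to the first rule that caught it, and the
exclusion log satisfies `|input| = |survivors| + sum(removals)` by
construction (and by test). Shifting cost is the mean RT of surviving
round-3 shift trials minus the mean RT of surviving rounds-1–2 trials
pooled into a single mean; inhibition cost replaces the minuend with the
surviving (incongruent) rounds-4–5 trials. Pooling the baseline weights
rounds by their surviving trial counts; `baseline = "round_means"` gives
the unweighted alternative. An empty required trial set yields a missing
score carrying its reason, never an error.

The filter chain is verified against an independent brute-force
re-implementation (sequential per-trial loops) with exact trial-set
equality on over a thousand randomized sessions spanning benign to
pathological parameter profiles.

# Statistical layer

* **Covariate screening.** `vif_screen()` reports `1/(1 - R²)` per
  covariate regressed on the others, flagging values above 10; perfectly
  collinear covariates report `Inf` rather than erroring. In the pipeline
  the most inflated covariate is dropped iteratively until none is
  flagged, mirroring the practice of omitting one of a collinear
  body-composition pair (fat and muscle percentage).
* **ANCOVA and EMMs.** `ancova()` fits `outcome ~ group + covariates` on
  complete cases (listwise, with the dropped count reported), uses
  sum-to-zero contrasts and a Type III group test (the convention of
  mainstream ANCOVA software, and the one that reproduces conventional
  df arithmetic: with the study's group sizes and three covariates,
  `df_error = 103 - 4 - 3 = 96`). Estimated marginal means come from
  the `emmeans` package with covariates at their complete-case grand means; a
  dichotomous covariate such as sex enters as a numeric 0/1 indicator so
  the reference grid holds it at the observed proportion. Pairwise
  comparisons over all six group pairs are Bonferroni-adjusted.
* **Effect sizes.** Published group summaries expose EMMs with standard
  errors, not raw data, so Cohen's *d* is backed out of the summaries:
  each group's SD is `SE × sqrt(n)`, pooled with `n - 1` weights, and the
  95% CI uses the large-sample SE
  `sqrt((n_a + n_b)/(n_a n_b) + d²/(2(n_a + n_b - 2)))`. On raw data this
  reduces exactly to the classical pooled-SD *d* (tested to 1e-9). Applied
  to the published SB-ratio summaries (Sports 0.587 ± 0.020, n = 34 vs
  Admin 0.468 ± 0.022, n = 24) it reproduces the published d = 1.06
  (95% CI 0.51–1.61) within rounding of the inputs.
* **Adherence tests.** Pearson chi-square without continuity correction
  on the adherent/non-adherent by group table; the per-group post-hoc uses
  Bonferroni-corrected adjusted standardized residuals (pairwise 2×2
  sub-tables are available as an option — the published analysis does not
  state which was used, and the residual test is the common default for
  singling one group out of k).
* **Associations.** Pearson, Spearman and Kendall tau-b correlations per
  activity-by-cognition cell on pairwise-complete cases with per-cell `n`
  reported (cognitive scores go missing cell-wise through the filter
  chain, so cells legitimately differ in `n`), plus one linear regression
  per cognitive outcome on the three activity variables. Degenerate cells
  (constant variable, n < 3) report `NA`, never an error.
* **Sensitivity subsets.** `subset_sensitivity()` re-runs the association
  suite excluding participants carrying each exclusion flag (medication,
  learning restriction, activity restriction, color blindness, age),
  skipping subsets under 10 participants with a warning, and reports
  significance-pattern agreement with the full sample.
* **Power.** `anova_power_n()` searches the smallest total `N` whose
  omnibus F test (df `k - 1`, `N - k`, noncentrality `f² N`) reaches the
  target power. By default the search is restricted to balanced designs
  (multiples of `k`), the convention of the G*Power program used for
  a-priori computations in this literature: for `k = 4`, `f = 0.40`,
  alpha 0.05, power 0.80 it returns 76 (the unconstrained minimum is 73,
  available via `equal_groups = FALSE`); the convention was verified
  against the standard `f = 0.25`, `k = 4` benchmark (180 vs 179).

Significance is reported in two tiers, 0.05 and 0.1 ("borderline"),
echoing the study convention.

# Numerical and test-design choices

* Tolerances: event-stream contiguity 1 ms by default (absorbing
  microsecond timestamp rounding through CSV round trips; genuine export
  gaps are orders larger); day completeness 0.5 s; generated streams
  conserve total time to well below 1e-6 s and are tested at that level.
* Seeds are explicit arguments everywhere; generators restore the
  caller's RNG state, and cohort-level functions derive per-participant
  seeds deterministically from one master seed, so whole runs are
  bit-reproducible (`run_study()` manifests are byte-identical across
  repeated runs with the same config).
* Monte-Carlo test sizes: generator convergence uses 200 simulated
  participants at 3 SE (the convergence tolerance adopted for all
  generator-recovery checks); ANCOVA recovery uses 200 replicate cohorts
  of 103 participants, requiring the replicate-mean EMM of every track and
  activity class to fall within 2 reported standard errors of the
  generating value and the omnibus test to reject in at least 95% of
  replicates; null calibration of the association suite uses 500
  replicates with binomial bounds per cell Bonferroni-adjusted across the
  nine cells, so the calibration check itself keeps a 5% false-alarm
  rate. Per-cell 95% bounds applied simultaneously to nine cells would
  fail about a third of the time on a perfectly calibrated
  implementation; the adjusted bounds test the same quantity without that
  built-in flakiness.
* Degenerate inputs have defined non-error behavior wherever the quantity
  is undefined rather than wrong: zero sedentary time (SB-ratio `NA`),
  zero pooled SD (missing effect size), constant correlation inputs
  (missing estimates), empty event streams (invalid participant), and
  excluded participants (missing scores with reasons).

# Known limitations

* The event generator's exponential dwell times understate the heavy tail
  of real sitting-bout distributions; SB-ratio levels are accordingly
  lower than real cohorts', though the bout cut-off logic is exact.
* Within a track, all synthetic participants share one daily-target
  profile; between-participant variance is purely sampling variance of a
  wear week. Group contrasts on synthetic data are therefore sharper than
  in real cohorts of the same size.
* No non-wear, compliance, or daylight-saving modelling; streams are
  complete by construction, and the valid-day rule is exercised through
  stream length and start date rather than through missingness patterns.
* The cognitive generator draws correctness independently of RT; speed to
  accuracy trade-offs are out of scope, as is practice-trial analysis.
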