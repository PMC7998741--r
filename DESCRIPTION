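Package: pabcog
Title: Posture-Event Accelerometry, Executive-Function Scoring, and Group
    Comparisons for Physical Activity Behavior Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes posture-event accelerometry (ActivPAL-style event
    exports) into daily physical-activity-behavior summaries: time in bed and
    time spent sitting, standing and stepping, sedentary-bout structure and
    the SB-ratio (proportion of sedentary time accrued in bouts shorter than
    30 minutes), cadence-based moderate-to-vigorous physical activity, and
    adherence to youth and adult physical-activity guidelines. Scores
    executive-function tests (letter-memory updating; color-shape shifting
    and inhibition costs) with an auditable multi-step reaction-time filter
    chain. Provides the accompanying statistical layer: variance-inflation
    covariate screening, one-way ANCOVA with estimated marginal means and
    Bonferroni pairwise comparisons, Cohen's d with confidence intervals,
    chi-square adherence tests with adjusted-residual post-hocs, correlation
    and regression association suites, subset sensitivity analyses, and
    a-priori sample-size computation from the noncentral F distribution.
    Includes a synthetic-data generator that emulates multi-day posture event
    streams and trial-level cognitive test sessions with known ground truth,
    so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
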