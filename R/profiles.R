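#' Construct a track activity profile
#'
#' A track profile is the simulation ground truth for one educational track:
#' the expected daily hours in each posture class, the mean episode ("bout")
#' durations that control how the day is broken up, the fraction of stepping
#' time performed at MVPA cadence (>= 100 steps/min), and the covariate
#' distributions of the track's students.
#'
#' @param track_name Track label, e.g. `"Sports"`.
#' @param target_daily_hours Named numeric vector with entries `sitting`,
#'   `standing`, `stepping`, `time_in_bed`; must sum to 24 (tolerance 1e-9).
#' @param mean_bout_minutes Named numeric vector of mean episode durations in
#'   minutes for the same classes (the `time_in_bed` entry is ignored: the
#'   night is generated as a single episode).
#' @param mvpa_fraction_of_stepping Proportion in `[0, 1]` of stepping time
#'   generated at cadence >= 100 steps/min.
#' @param covariate_params List with elements `age_mean`, `age_sd`,
#'   `female_prop`, `bmi_mean`, `bmi_sd`, `fat_mean`, `fat_sd`,
#'   `muscle_mean`, `muscle_sd` and optionally `fat_muscle_cor`
#'   (default -0.85; fat and muscle percentage are strongly negatively
#'   correlated in body-composition data).
#' @return An object of class `track_profile`.
#' @export
track_profile <- function(track_name,
                          target_daily_hours,
                          mean_bout_minutes,
                          mvpa_fraction_of_stepping,
                          covariate_params) {
  stopifnot(is.character(track_name), length(track_name) == 1L)
  target_daily_hours <- target_daily_hours[.activity_classes]
  if (anyNA(target_daily_hours)) {
    stop("`target_daily_hours` must name all of: ",
         paste(.activity_classes, collapse = ", "), call. = FALSE)
  }
  if (any(target_daily_hours < 0)) {
    stop("daily-hour targets must be non-negative", call. = FALSE)
  }
  if (abs(sum(target_daily_hours) - 24) > 1e-9) {
    stop(sprintf("`target_daily_hours` must sum to 24 h (got %.12f)",
                 sum(target_daily_hours)), call. = FALSE)
  }
  if (target_daily_hours[["time_in_bed"]] >= 24) {
    stop("time_in_bed must be < 24 h/day", call. = FALSE)
  }
  mean_bout_minutes <- mean_bout_minutes[intersect(names(mean_bout_minutes),
                                                   .activity_classes)]
  if (any(mean_bout_minutes <= 0)) {
    stop("mean bout durations must be positive", call. = FALSE)
  }
  assert_prob(mvpa_fraction_of_stepping, "mvpa_fraction_of_stepping")
  assert_prob(covariate_params$female_prop, "female_prop")
  num <- unlist(covariate_params[grepl("_(mean|sd)$", names(covariate_params))])
  if (any(!is.finite(num))) stop("covariate means/SDs must be finite", call. = FALSE)
  if (any(unlist(covariate_params[grepl("_sd$", names(covariate_params))]) < 0)) {
    stop("covariate SDs must be >= 0", call. = FALSE)
  }
  covariate_params$fat_muscle_cor <- covariate_params$fat_muscle_cor %||% -0.85
  structure(
    list(track_name = track_name,
         target_daily_hours = target_daily_hours,
         mean_bout_minutes = mean_bout_minutes,
         mvpa_fraction_of_stepping = mvpa_fraction_of_stepping,
         covariate_params = covariate_params),
    class = "track_profile"
  )
}

#' Default track profiles for the four vocational-education tracks
#'
#' Daily-hour targets are the published covariate-adjusted group means for
#' Hairdresser, Admin, Sports and Nursing students (sitting 7.65 / 9.76 /
#' 7.86 / 9.23 h, standing 5.14 / 3.12 / 3.94 / 4.23 h, stepping 1.72 / 1.78
#' / 2.61 / 2.16 h); because adjusted means need not close the 24-h day
#' exactly, the residual (at most 0.01 h) is absorbed into `time_in_bed`.
#' Covariate distributions follow the cohort's descriptive table. Mean
#' sitting-bout durations and MVPA fractions are free simulation parameters,
#' chosen so the tracks differ in bout structure (Sports: short, frequently
#' interrupted sitting; Admin: prolonged sitting) and guideline adherence.
#'
#' @return Named list of four [track_profile()] objects.
#' @export
default_track_profiles <- function() {
  mk_hours <- function(sit, stand, step) {
    c(sitting = sit, standing = stand, stepping = step,
      time_in_bed = 24 - sit - stand - step)
  }
  list(
    Hairdresser = track_profile(
      "Hairdresser",
      mk_hours(7.65, 5.14, 1.72),
      c(sitting = 18, standing = 10, stepping = 5),
      mvpa_fraction_of_stepping = 0.25,
      covariate_params = list(age_mean = 19.5, age_sd = 2.3, female_prop = 1.0,
                              bmi_mean = 21.8, bmi_sd = 3.7,
                              fat_mean = 30.9, fat_sd = 7.2,
                              muscle_mean = 28.3, muscle_sd = 2.4)),
    Admin = track_profile(
      "Admin",
      mk_hours(9.76, 3.12, 1.78),
      c(sitting = 22, standing = 7, stepping = 5),
      mvpa_fraction_of_stepping = 0.25,
      covariate_params = list(age_mean = 18.6, age_sd = 2.5, female_prop = 16 / 24,
                              bmi_mean = 23.8, bmi_sd = 4.0,
                              fat_mean = 29.0, fat_sd = 9.9,
                              muscle_mean = 31.1, muscle_sd = 7.0)),
    Sports = track_profile(
      "Sports",
      mk_hours(7.86, 3.94, 2.61),
      c(sitting = 13, standing = 8, stepping = 6),
      mvpa_fraction_of_stepping = 0.55,
      covariate_params = list(age_mean = 17.6, age_sd = 0.6, female_prop = 13 / 34,
                              bmi_mean = 22.7, bmi_sd = 2.3,
                              fat_mean = 22.5, fat_sd = 7.3,
                              muscle_mean = 36.4, muscle_sd = 6.0)),
    Nursing = track_profile(
      "Nursing",
      mk_hours(9.23, 4.23, 2.16),
      c(sitting = 18, standing = 9, stepping = 5),
      mvpa_fraction_of_stepping = 0.35,
      covariate_params = list(age_mean = 22.6, age_sd = 4.9, female_prop = 16 / 19,
                              bmi_mean = 23.4, bmi_sd = 4.0,
                              fat_mean = 30.7, fat_sd = 9.7,
                              muscle_mean = 30.1, muscle_sd = 6.0))
  )
}

#' Construct a cognitive performance profile
#'
#' Ground-truth parameters for simulated cognitive test sessions. Reaction
#' times are lognormal around `base_rt_ms`; task-switch trials add
#' `shift_cost_ms` and incongruent bivalent trials add `inhibition_cost_ms`.
#' Contaminant responses are injected at `guess_rate` (anticipations
#' < 170 ms) and `lapse_rate` (lapses > 5000 ms). For the letter-memory
#' test, each of the three target letters is recalled independently with
#' probability `updating_recall_prob`.
#'
#' @param base_rt_ms Mean reaction time on single-task trials, ms (> 170).
#' @param shift_cost_ms Added mean RT on task-switch trials, ms.
#' @param inhibition_cost_ms Added mean RT on incongruent trials, ms.
#' @param rt_cv Coefficient of variation of the lognormal RT distribution,
#'   in (0, 1).
#' @param error_rate,lapse_rate,guess_rate Probabilities in `[0, 1]`.
#' @param updating_recall_prob Probability a target letter is recalled.
#' @return An object of class `cognitive_profile`.
#' @export
cognitive_profile <- function(base_rt_ms = 600,
                              shift_cost_ms = 300,
                              inhibition_cost_ms = 150,
                              rt_cv = 0.25,
                              error_rate = 0.06,
                              lapse_rate = 0.01,
                              guess_rate = 0.01,
                              updating_recall_prob = 0.75) {
  if (!is.numeric(base_rt_ms) || base_rt_ms <= 170) {
    stop("`base_rt_ms` must exceed 170 ms", call. = FALSE)
  }
  if (rt_cv <= 0 || rt_cv >= 1) stop("`rt_cv` must be in (0, 1)", call. = FALSE)
  assert_prob(error_rate, "error_rate")
  assert_prob(lapse_rate, "lapse_rate")
  assert_prob(guess_rate, "guess_rate")
  if (lapse_rate + guess_rate > 1) {
    stop("`lapse_rate` + `guess_rate` must not exceed 1", call. = FALSE)
  }
  assert_prob(updating_recall_prob, "updating_recall_prob")
  structure(
    list(base_rt_ms = base_rt_ms, shift_cost_ms = shift_cost_ms,
         inhibition_cost_ms = inhibition_cost_ms, rt_cv = rt_cv,
         error_rate = error_rate, lapse_rate = lapse_rate,
         guess_rate = guess_rate,
         updating_recall_prob = updating_recall_prob),
    class = "cognitive_profile"
  )
}
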