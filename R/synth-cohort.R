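#' Generate a synthetic participant cohort
#'
#' Draws participants per track with sex from the track's female proportion
#' and age, fat percentage, muscle percentage and BMI from truncated normal
#' distributions with the track's means and SDs. Muscle percentage is drawn
#' conditionally on fat percentage with the profile's `fat_muscle_cor`
#' (default -0.85), mimicking the strong negative correlation between the
#' two body-composition measures that motivates multicollinearity screening
#' downstream.
#'
#' @param n_per_track Named integer vector, track -> count (all >= 1).
#' @param profiles Named list of [track_profile()] objects covering every
#'   track named in `n_per_track`.
#' @param seed Integer seed; calls with the same arguments are
#'   bit-reproducible.
#' @return A data.frame with columns `participant_id`, `track` (factor),
#'   `sex` (`"F"`/`"M"`), `female` (0/1), `age`, `fat_pct`, `muscle_pct`,
#'   `bmi`.
#' @examples
#' cohort <- generate_cohort(c(Sports = 5, Admin = 5), seed = 1)
#' @export
generate_cohort <- function(n_per_track,
                            profiles = default_track_profiles(),
                            seed) {
  if (is.null(names(n_per_track)) || any(!nzchar(names(n_per_track)))) {
    stop("`n_per_track` must be a named vector (track -> count)", call. = FALSE)
  }
  if (any(n_per_track < 1)) stop("all track counts must be >= 1", call. = FALSE)
  unknown <- setdiff(names(n_per_track), names(profiles))
  if (length(unknown)) {
    stop("no profile for track(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    parts <- lapply(names(n_per_track), function(tr) {
      n <- as.integer(n_per_track[[tr]])
      cp <- profiles[[tr]]$covariate_params
      female <- rbinom(n, 1L, cp$female_prop)
      age <- rtruncnorm(n, cp$age_mean, cp$age_sd, lower = 16, upper = 40)
      fat <- rtruncnorm(n, cp$fat_mean, cp$fat_sd, lower = 5, upper = 55)
      # conditional normal: muscle | fat, with the profile's correlation
      rho <- cp$fat_muscle_cor
      mu_cond <- cp$muscle_mean +
        rho * cp$muscle_sd / max(cp$fat_sd, 1e-12) * (fat - cp$fat_mean)
      sd_cond <- cp$muscle_sd * sqrt(max(0, 1 - rho^2))
      muscle <- vapply(mu_cond, function(m)
        rtruncnorm(1L, m, sd_cond, lower = 15, upper = 60), numeric(1))
      bmi <- rtruncnorm(n, cp$bmi_mean, cp$bmi_sd, lower = 14, upper = 45)
      data.frame(track = tr, female = female, age = age, fat_pct = fat,
                 muscle_pct = muscle, bmi = bmi, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    out$participant_id <- sprintf("P%03d", seq_len(nrow(out)))
    out$sex <- ifelse(out$female == 1L, "F", "M")
    out$track <- factor(out$track, levels = names(profiles))
    out[, c("participant_id", "track", "sex", "female", "age",
            "fat_pct", "muscle_pct", "bmi")]
  })
}
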