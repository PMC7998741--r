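#' Generate a synthetic posture event stream
#'
#' Simulates a multi-day, gapless sequence of posture events (sitting,
#' standing, stepping, time in bed) for one participant as an
#' alternating-state renewal process. One nightly in-bed episode starts
#' around 23:00 (uniform jitter of +/- 30 min) with duration close to the
#' profile's `time_in_bed` target; waking time is filled with episodes whose
#' class is drawn with probability proportional to the renewal rate
#' (daily-hours target divided by mean episode duration) and whose dwell
#' times are exponential with the class's mean bout duration, so expected
#' daily totals per class equal `target_daily_hours`. Stepping episodes
#' carry step counts such that, in expectation, a fraction
#' `mvpa_fraction_of_stepping` of stepping time is at cadence
#' >= 100 steps/min and the remainder below it.
#'
#' The stream spans exactly `n_days` * 24 h with no gaps or overlaps; the
#' first and last events are truncated at the stream boundaries.
#'
#' @param profile A [track_profile()].
#' @param n_days Number of calendar days (>= 1).
#' @param seed Integer seed.
#' @param start_date First calendar day (default 2024-01-01, a Monday, so a
#'   7-day stream holds five weekdays and a full weekend).
#' @return A data.frame with columns `start` (POSIXct, UTC), `duration_s`,
#'   `activity`, `steps`.
#' @export
generate_event_stream <- function(profile, n_days, seed,
                                  start_date = as.Date("2024-01-01")) {
  stopifnot(inherits(profile, "track_profile"))
  if (!is.numeric(n_days) || n_days < 1) stop("`n_days` must be >= 1", call. = FALSE)
  n_days <- as.integer(n_days)
  tgt <- profile$target_daily_hours
  if (tgt[["time_in_bed"]] >= 24) {
    stop("infeasible profile: time_in_bed >= 24 h/day", call. = FALSE)
  }
  total_s <- n_days * 86400

  with_seed(seed, {
    bed_s <- tgt[["time_in_bed"]] * 3600
    # nightly schedule: bedtime_d at 23:00 +/- 30 min of day d; the virtual
    # night before day 1 places the stream's opening in-bed episode
    bedtimes <- if (bed_s > 0) {
      (0:(n_days - 1) + 1) * 86400 - 3600 + runif(n_days, -1800, 1800)
    } else {
      numeric(0)
    }
    bed_durs <- if (bed_s > 0) {
      pmax(0.25 * bed_s, bed_s + rnorm(n_days + 1L, 0, 900))
    } else {
      numeric(0)
    }
    wake0 <- if (bed_s > 0) {
      max(0, bed_durs[1L] - 3600 + runif(1, -1800, 1800))
    } else {
      0
    }

    segments <- list()
    push <- function(cls, dur) {
      keep <- dur > 1e-9
      if (any(keep)) {
        segments[[length(segments) + 1L]] <<-
          list(cls = cls[keep], dur = dur[keep])
      }
    }
    if (wake0 > 0) push("time_in_bed", wake0)

    cursor <- wake0
    night_idx <- 1L
    while (cursor < total_s - 1e-9) {
      next_bed <- if (night_idx <= length(bedtimes)) bedtimes[night_idx] else Inf
      wake_end <- min(next_bed, total_s)
      if (wake_end > cursor) {
        w <- fill_waking_interval(profile, wake_end - cursor)
        push(w$cls, w$dur)
        cursor <- wake_end
      }
      if (is.finite(next_bed) && cursor < total_s - 1e-9) {
        dur <- min(bed_durs[night_idx + 1L], total_s - cursor)
        push("time_in_bed", dur)
        cursor <- cursor + dur
        night_idx <- night_idx + 1L
      }
    }

    cls <- unlist(lapply(segments, `[[`, "cls"))
    dur <- unlist(lapply(segments, `[[`, "dur"))
    # merge adjacent same-class episodes (a bout boundary needs a state change)
    grp <- cumsum(c(TRUE, cls[-1L] != cls[-length(cls)]))
    dur <- as.numeric(tapply(dur, grp, sum)[as.character(unique(grp))])
    cls <- cls[!duplicated(grp)]
    # pin the final episode so the stream closes the window exactly
    dur[length(dur)] <- total_s - sum(dur[-length(dur)])

    steps <- numeric(length(dur))
    is_step <- cls == "stepping"
    if (any(is_step)) {
      d_min <- dur[is_step] / 60
      hi <- runif(sum(is_step)) < profile$mvpa_fraction_of_stepping
      cadence <- numeric(sum(is_step))
      cadence[hi] <- rtruncnorm(sum(hi), 115, 8, lower = 100.5, upper = 160)
      cadence[!hi] <- rtruncnorm(sum(!hi), 70, 12, lower = 20, upper = 99)
      st <- numeric(sum(is_step))
      # floor(100 d) + 1 keeps cadence strictly above the 100 steps/min
      # threshold, so classification is stable under timestamp rounding
      st[hi] <- pmax(ceiling(cadence[hi] * d_min[hi]),
                     floor(100 * d_min[hi]) + 1)
      st[!hi] <- pmax(0, pmin(floor(cadence[!hi] * d_min[!hi]),
                              ceiling(100 * d_min[!hi]) - 1))
      steps[is_step] <- st
    }

    t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
    data.frame(
      start = t0 + c(0, cumsum(dur[-length(dur)])),
      duration_s = dur,
      activity = cls,
      steps = steps,
      stringsAsFactors = FALSE
    )
  })
}

# Fill one waking interval of `len` seconds with sitting/standing/stepping
# episodes. Class probabilities are proportional to target_hours / mean_bout
# (renewal rates), which makes expected time shares proportional to the
# daily-hour targets; dwell times are exponential.
fill_waking_interval <- function(profile, len) {
  tgt <- profile$target_daily_hours[.waking_classes]
  active <- names(tgt)[tgt > 0]
  if (!length(active)) {
    # a profile with all waking targets zero cannot reach here (time_in_bed
    # < 24 is enforced), but close the interval defensively
    return(list(cls = "sitting", dur = len))
  }
  mb <- profile$mean_bout_minutes
  mean_s <- vapply(active, function(a) (mb[[a]] %||% 15) * 60, numeric(1))
  rate <- as.numeric(tgt[active]) / mean_s
  p <- rate / sum(rate)
  p_time <- as.numeric(tgt[active]) / sum(tgt[active])
  mean_dwell <- sum(p * mean_s)

  # time-stationary start: the first episode's class is drawn by time share
  # (its exponential dwell is memoryless, so the residual-life distribution
  # is the dwell distribution itself); later classes are drawn by renewal
  # rate. This makes the expected time per class in any finite window
  # exactly proportional to the daily-hour targets.
  first <- sample.int(length(active), 1L, prob = p_time)
  cls <- active[first]
  dur <- rexp(1L, rate = 1 / mean_s[first])
  while (sum(dur) < len) {
    k <- max(16L, ceiling((len - sum(dur)) / mean_dwell * 1.4))
    idx <- sample.int(length(active), k, replace = TRUE, prob = p)
    cls <- c(cls, active[idx])
    dur <- c(dur, rexp(k, rate = 1 / mean_s[idx]))
  }
  cum <- cumsum(dur)
  cut <- which(cum >= len)[1L]
  cls <- cls[seq_len(cut)]
  dur <- dur[seq_len(cut)]
  dur[cut] <- len - if (cut > 1L) cum[cut - 1L] else 0
  list(cls = cls, dur = dur)
}

#' Generate posture event streams for a whole cohort
#'
#' @param cohort Data.frame from [generate_cohort()].
#' @param profiles Named list of [track_profile()] objects.
#' @param n_days Days of wear per participant (default 7).
#' @param seed Master seed; per-participant seeds are derived from it.
#' @param start_date See [generate_event_stream()].
#' @return A data.frame of events with a `participant_id` column prepended.
#' @export
generate_cohort_events <- function(cohort, profiles = default_track_profiles(),
                                   n_days = 7, seed,
                                   start_date = as.Date("2024-01-01")) {
  seeds <- derive_seeds(seed, nrow(cohort))
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    ev <- generate_event_stream(profiles[[as.character(cohort$track[i])]],
                                n_days = n_days, seed = seeds[i],
                                start_date = start_date)
    cbind(participant_id = cohort$participant_id[i], ev,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
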