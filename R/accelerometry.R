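#' Validate a posture event stream
#'
#' Checks the event-stream contract: positive durations, known activity
#' classes, zero steps on non-stepping events, and (per participant) events
#' sorted, non-overlapping and contiguous. Violations raise an error naming
#' the offending rows.
#'
#' @param events Data.frame with columns `start` (POSIXct), `duration_s`,
#'   `activity`, `steps`, and optionally `participant_id`.
#' @param tol Contiguity tolerance in seconds. The default (1 ms) absorbs
#'   timestamp rounding from text serialization; genuine gaps or overlaps
#'   in event exports are orders of magnitude larger.
#' @return `events`, invisibly.
#' @export
validate_event_stream <- function(events, tol = 1e-3) {
  req <- c("start", "duration_s", "activity", "steps")
  missing_cols <- setdiff(req, names(events))
  if (length(missing_cols)) {
    stop("event table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(events$duration_s <= 0)) {
    stop("event(s) with non-positive duration at row(s): ",
         paste(head(which(events$duration_s <= 0), 5L), collapse = ", "),
         call. = FALSE)
  }
  bad_cls <- !events$activity %in% .activity_classes
  if (any(bad_cls)) {
    stop("unknown activity class at row(s): ",
         paste(head(which(bad_cls), 5L), collapse = ", "), call. = FALSE)
  }
  bad_steps <- events$activity != "stepping" & events$steps != 0
  if (any(bad_steps)) {
    stop("non-stepping event(s) carry steps at row(s): ",
         paste(head(which(bad_steps), 5L), collapse = ", "), call. = FALSE)
  }
  ids <- if ("participant_id" %in% names(events)) events$participant_id else
    rep("all", nrow(events))
  for (id in unique(ids)) {
    idx <- which(ids == id)
    st <- as.numeric(events$start[idx])
    du <- events$duration_s[idx]
    if (is.unsorted(st, strictly = FALSE)) {
      first <- idx[which(diff(st) < 0)[1L]]
      stop(sprintf("events out of order for '%s' at rows %d/%d",
                   id, first, first + 1L), call. = FALSE)
    }
    gap <- st[-1L] - (st[-length(st)] + du[-length(du)])
    bad <- which(abs(gap) > tol)
    if (length(bad)) {
      kind <- if (gap[bad[1L]] > 0) "gap" else "overlap"
      stop(sprintf("%s between events for '%s' at rows %d/%d (%.6f s)",
                   kind, id, idx[bad[1L]], idx[bad[1L] + 1L], gap[bad[1L]]),
           call. = FALSE)
    }
  }
  invisible(events)
}

# Assign sedentary bout ids on the *unsplit* stream: a bout is a maximal run
# of consecutive sitting events; any other class (including time in bed)
# terminates it. Returns per-event bout id (NA off-bout) and each bout's
# total duration in minutes, in stream order. Midnight does not break a bout.
sedentary_bout_map <- function(activity, duration_s) {
  sit <- activity == "sitting"
  r <- rle(sit)
  run_id <- rep(seq_along(r$values), r$lengths)
  sit_runs <- which(r$values)
  bout_id <- rep(NA_integer_, length(activity))
  bout_id[sit] <- match(run_id[sit], sit_runs)
  n_bouts <- length(sit_runs)
  totals <- numeric(n_bouts)
  if (n_bouts) {
    sums <- tapply(duration_s[sit], bout_id[sit], sum)
    totals[as.integer(names(sums))] <- as.numeric(sums)
  }
  list(bout_id = bout_id, bout_min = totals / 60)
}

#' Detect sedentary bouts in an event stream
#'
#' A sedentary bout is a maximal run of consecutive sitting events; standing,
#' stepping and time in bed all terminate a bout (time in bed is reported as
#' its own outcome class and is not sedentary time). Bout length is the sum
#' of the run's durations; midnight does not break a bout.
#'
#' @param events Event stream for one participant (see
#'   [validate_event_stream()]).
#' @return Numeric vector of bout durations in minutes, in stream order.
#' @examples
#' ev <- data.frame(
#'   start = as.POSIXct("2024-01-01", tz = "UTC") + c(0, 600, 660),
#'   duration_s = c(600, 60, 600),
#'   activity = c("sitting", "standing", "sitting"), steps = 0)
#' detect_sedentary_bouts(ev)  # 10, 10
#' @export
detect_sedentary_bouts <- function(events) {
  validate_event_stream(events)
  sedentary_bout_map(events$activity, events$duration_s)$bout_min
}

#' Sedentary-behavior ratio
#'
#' The SB-ratio is the proportion of total sedentary time accrued in bouts
#' shorter than `cutoff_min` minutes (strictly below the cut-off: a bout of
#' exactly 30 min counts as prolonged). Higher values mean more interrupted
#' sitting.
#'
#' @param bout_min Numeric vector of bout durations in minutes.
#' @param cutoff_min Bout cut-off in minutes (default 30).
#' @return Proportion in `[0, 1]`, or `NA` when total sedentary time is zero.
#' @export
sb_ratio <- function(bout_min, cutoff_min = 30) {
  total <- sum(bout_min)
  if (!length(bout_min) || total <= 0) return(NA_real_)
  sum(bout_min[bout_min < cutoff_min]) / total
}

#' MVPA minutes from stepping cadence
#'
#' Each stepping event's cadence is `steps / duration-in-minutes`; the event
#' counts as moderate-to-vigorous physical activity when cadence reaches
#' `cadence_threshold` (default 100 steps/min, the conventional >= 3 MET
#' walking cadence).
#'
#' @param events Event table (any mix of classes; only stepping contributes).
#' @param cadence_threshold Steps/min cut-point.
#' @return MVPA minutes (sum of qualifying stepping durations).
#' @export
mvpa_minutes <- function(events, cadence_threshold = 100) {
  step <- events[events$activity == "stepping", , drop = FALSE]
  if (!nrow(step)) return(0)
  if (any(step$duration_s <= 0)) {
    stop("stepping event with non-positive duration", call. = FALSE)
  }
  cadence <- step$steps / (step$duration_s / 60)
  sum(step$duration_s[cadence >= cadence_threshold]) / 60
}

# UTC offset (seconds) of the stream's local frame at its first timestamp.
# A fixed offset per stream (no DST transitions) keeps day arithmetic
# vectorized; the default UTC frame has offset 0.
tz_offset <- function(t0, tz) {
  lt <- as.POSIXlt(t0, tz = tz)
  off <- lt$gmtoff
  if (is.null(off) || is.na(off)) {
    # fall back to comparing wall-clock renderings
    wall <- as.POSIXct(format(t0, "%Y-%m-%d %H:%M:%S", tz = tz), tz = "UTC")
    off <- as.numeric(difftime(wall, t0, units = "secs"))
  }
  off
}

#' Split a posture event stream at local midnights
#'
#' Events crossing midnight are cut at the day boundary with durations and
#' step counts apportioned pro rata (cadence is therefore preserved).
#' Sedentary bout identity is assigned before splitting, so a bout's total
#' length is unaffected by the day boundary while its time is attributed to
#' the day(s) it occupies.
#'
#' @param events Event stream (one or many participants); validated first.
#' @param tz Time zone defining midnight (default `"UTC"`; a fixed offset is
#'   assumed within a stream).
#' @return Data.frame of event pieces with added columns `date`,
#'   `is_weekend`, `event_id`, `bout_id`, `bout_total_min`.
#' @export
split_events_by_day <- function(events, tz = "UTC") {
  validate_event_stream(events)
  if (!"participant_id" %in% names(events)) events$participant_id <- "P1"
  zoff <- tz_offset(events$start[1L], tz)
  parts <- split(seq_len(nrow(events)), events$participant_id)
  pieces <- lapply(parts, function(idx) {
    ev <- events[idx, , drop = FALSE]
    bm <- sedentary_bout_map(ev$activity, ev$duration_s)
    st <- as.numeric(ev$start)
    en <- st + ev$duration_s
    d_start <- floor((st + zoff + 1e-9) / 86400)
    d_end <- floor((en + zoff - 1e-9) / 86400)
    n_cut <- pmax(0L, d_end - d_start)
    simple <- n_cut == 0L
    base <- data.frame(
      participant_id = ev$participant_id, start_s = st,
      duration_s = ev$duration_s, activity = ev$activity, steps = ev$steps,
      event_id = idx, bout_id = bm$bout_id,
      day_idx = d_start, stringsAsFactors = FALSE
    )
    res <- base[simple, , drop = FALSE]
    extra <- lapply(which(!simple), function(i) {
      cuts <- (d_start[i] + seq_len(n_cut[i])) * 86400 - zoff
      b <- c(st[i], cuts, en[i])
      durs <- diff(b)
      keep <- durs > 1e-9
      piece <- base[rep(i, sum(keep)), , drop = FALSE]
      piece$start_s <- b[-length(b)][keep]
      piece$duration_s <- durs[keep]
      piece$steps <- ev$steps[i] * durs[keep] / ev$duration_s[i]
      piece$day_idx <- floor((piece$start_s + zoff + 1e-9) / 86400)
      piece
    })
    res <- do.call(rbind, c(list(res), extra))
    res <- res[order(res$start_s), , drop = FALSE]
    res$bout_total_min <- ifelse(is.na(res$bout_id), NA_real_,
                                 bm$bout_min[res$bout_id])
    res
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res$start <- as.POSIXct(res$start_s, origin = "1970-01-01", tz = tz)
  res$date <- as.Date(res$day_idx, origin = "1970-01-01")
  dow <- (res$day_idx + 4) %% 7  # 0 = Sunday (1970-01-01 was a Thursday)
  res$is_weekend <- dow %in% c(0, 6)
  res$start_s <- NULL
  res$day_idx <- NULL
  res
}

#' Per-day activity records
#'
#' Aggregates day-split event pieces into one record per participant-day:
#' hours per activity class, completeness (the full 24 h covered), MVPA
#' minutes, and attributed sedentary time split by bout length.
#'
#' @param split_events Output of [split_events_by_day()].
#' @param cadence_threshold Steps/min cut-point for MVPA.
#' @param bout_cutoff_min Sedentary bout cut-off in minutes.
#' @return Data.frame with one row per participant-day and columns
#'   `participant_id`, `date`, `is_weekend`, `sitting_h`, `standing_h`,
#'   `stepping_h`, `time_in_bed_h`, `total_h`, `complete`, `mvpa_minutes`,
#'   `sedentary_min`, `sedentary_short_min` (sitting time in bouts shorter
#'   than the cut-off, attributed to this day).
#' @export
day_records <- function(split_events, cadence_threshold = 100,
                        bout_cutoff_min = 30) {
  se <- split_events
  key <- paste(se$participant_id, se$date, sep = "\r")
  ukey <- !duplicated(key)
  per_class <- function(mask, x) {
    out <- rowsum(ifelse(mask, x, 0), key, reorder = FALSE)
    out[, 1L]
  }
  sit <- se$activity == "sitting"
  step <- se$activity == "stepping"
  cadence <- ifelse(step & se$duration_s > 0,
                    se$steps / (se$duration_s / 60), 0)
  out <- data.frame(
    participant_id = se$participant_id[ukey],
    date = se$date[ukey],
    is_weekend = se$is_weekend[ukey],
    sitting_h = per_class(sit, se$duration_s) / 3600,
    standing_h = per_class(se$activity == "standing", se$duration_s) / 3600,
    stepping_h = per_class(step, se$duration_s) / 3600,
    time_in_bed_h = per_class(se$activity == "time_in_bed",
                              se$duration_s) / 3600,
    mvpa_minutes = per_class(step & cadence >= cadence_threshold,
                             se$duration_s) / 60,
    sedentary_min = per_class(sit, se$duration_s) / 60,
    sedentary_short_min = per_class(
      sit & !is.na(se$bout_total_min) & se$bout_total_min < bout_cutoff_min,
      se$duration_s) / 60,
    stringsAsFactors = FALSE
  )
  out$total_h <- out$sitting_h + out$standing_h + out$stepping_h +
    out$time_in_bed_h
  # a day is complete when the full 24 h are covered; the 0.5 s slack
  # absorbs timestamp rounding from text serialization
  out$complete <- abs(out$total_h - 24) < 0.5 / 3600
  out <- out[order(out$participant_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Physical-activity guideline adherence
#'
#' Youth rule: at least 60 min of MVPA on *every* complete measured day.
#' Adult rule: at least 150 min of MVPA per week on average, i.e. mean daily
#' MVPA over complete days times seven reaching 150.
#'
#' @param days [day_records()] rows for one participant.
#' @param rule `"youth"` or `"adult"`.
#' @return Logical, or `NA` when the participant has no complete day.
#' @export
guideline_adherence <- function(days, rule = c("youth", "adult")) {
  rule <- match.arg(rule)
  days <- days[days$complete, , drop = FALSE]
  if (!nrow(days)) return(NA)
  if (rule == "youth") {
    all(days$mvpa_minutes >= 60)
  } else {
    mean(days$mvpa_minutes) * 7 >= 150
  }
}

#' Summarize participants' physical activity behavior
#'
#' Applies the validity rule (at least `min_weekdays` complete weekdays and
#' `min_weekend_days` complete weekend days), then computes each
#' participant's mean daily hours per activity class over complete days, the
#' SB-ratio, mean daily MVPA minutes, and guideline adherence flags. Invalid
#' participants are retained with `valid = FALSE` (and `NA` adherence) so
#' that attrition stays auditable; downstream analyses subset on `valid`.
#'
#' The SB-ratio is pooled over the participant's complete days by default
#' (total short-bout sitting time divided by total sitting time, with bout
#' length judged on the unbroken bout); `sb_ratio_method = "per_day"`
#' averages the daily ratios instead.
#'
#' @param events Event stream for one or more participants.
#' @param bout_cutoff_min,cadence_threshold Processing constants (defaults
#'   30 min and 100 steps/min).
#' @param min_weekdays,min_weekend_days Validity rule (defaults 2 and 2).
#' @param sb_ratio_method `"pooled"` (default) or `"per_day"`.
#' @param tz Time zone defining midnight.
#' @return Data.frame with one row per participant: `participant_id`,
#'   `n_valid_weekdays`, `n_valid_weekend_days`, `valid`, `sitting_h`,
#'   `standing_h`, `stepping_h`, `time_in_bed_h`, `sb_ratio`, `mvpa_min`,
#'   `adheres_youth`, `adheres_adult`.
#' @export
summarize_participants <- function(events,
                                   bout_cutoff_min = 30,
                                   cadence_threshold = 100,
                                   min_weekdays = 2L,
                                   min_weekend_days = 2L,
                                   sb_ratio_method = c("pooled", "per_day"),
                                   tz = "UTC") {
  sb_ratio_method <- match.arg(sb_ratio_method)
  if (!nrow(events)) return(empty_pab(character(0)))
  if (!"participant_id" %in% names(events)) events$participant_id <- "P1"
  all_ids <- unique(events$participant_id)
  sp <- split_events_by_day(events, tz = tz)
  days <- day_records(sp, cadence_threshold = cadence_threshold,
                      bout_cutoff_min = bout_cutoff_min)
  rows <- lapply(all_ids, function(id) {
    d <- days[days$participant_id == id, , drop = FALSE]
    comp <- d[d$complete, , drop = FALSE]
    n_wd <- sum(!comp$is_weekend)
    n_we <- sum(comp$is_weekend)
    valid <- n_wd >= min_weekdays && n_we >= min_weekend_days
    if (nrow(comp)) {
      means <- colMeans(comp[, c("sitting_h", "standing_h", "stepping_h",
                                 "time_in_bed_h")])
      sbr <- if (sb_ratio_method == "pooled") {
        if (sum(comp$sedentary_min) > 0)
          sum(comp$sedentary_short_min) / sum(comp$sedentary_min)
        else NA_real_
      } else {
        r <- comp$sedentary_short_min[comp$sedentary_min > 0] /
          comp$sedentary_min[comp$sedentary_min > 0]
        if (!length(r)) NA_real_ else mean(r)
      }
      mvpa <- mean(comp$mvpa_minutes)
    } else {
      means <- rep(NA_real_, 4L)
      sbr <- NA_real_
      mvpa <- NA_real_
    }
    data.frame(
      participant_id = id,
      n_valid_weekdays = n_wd, n_valid_weekend_days = n_we, valid = valid,
      sitting_h = means[[1L]], standing_h = means[[2L]],
      stepping_h = means[[3L]], time_in_bed_h = means[[4L]],
      sb_ratio = sbr, mvpa_min = mvpa,
      adheres_youth = if (valid) guideline_adherence(d, "youth") else NA,
      adheres_adult = if (valid) guideline_adherence(d, "adult") else NA,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_pab <- function(ids) {
  data.frame(participant_id = ids, n_valid_weekdays = integer(length(ids)),
             n_valid_weekend_days = integer(length(ids)),
             valid = logical(length(ids)),
             sitting_h = NA_real_[seq_along(ids)],
             standing_h = NA_real_[seq_along(ids)],
             stepping_h = NA_real_[seq_along(ids)],
             time_in_bed_h = NA_real_[seq_along(ids)],
             sb_ratio = NA_real_[seq_along(ids)],
             mvpa_min = NA_real_[seq_along(ids)],
             adheres_youth = NA[seq_along(ids)],
             adheres_adult = NA[seq_along(ids)],
             stringsAsFactors = FALSE)
}
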