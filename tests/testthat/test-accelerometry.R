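test_that("stream validation names the offending pair", {
  ev <- make_stream(c("sitting", "standing"), c(30, 30))
  expect_silent(validate_event_stream(ev))

  gap <- ev; gap$start[2] <- gap$start[2] + 60
  expect_error(validate_event_stream(gap), "gap between events.*rows 1/2")
  overlap <- ev; overlap$start[2] <- overlap$start[2] - 60
  expect_error(validate_event_stream(overlap), "overlap")
  unsorted <- ev[2:1, ]
  expect_error(validate_event_stream(unsorted), "out of order")
  stepsbad <- ev; stepsbad$steps[1] <- 10
  expect_error(validate_event_stream(stepsbad), "carry steps")
})

test_that("midnight splitting conserves time and apportions steps pro rata", {
  # one 48 h sitting event starting Monday 00:00
  ev <- make_stream("sitting", 48 * 60)
  days <- day_records(split_events_by_day(ev))
  expect_equal(nrow(days), 2)
  expect_true(all(days$complete))
  expect_equal(days$sitting_h, c(24, 24))

  # stepping 23:30-00:30 with 60 steps: half on each side of midnight
  ev2 <- make_stream(c("sitting", "stepping"), c(23.5 * 60, 60),
                     steps = c(0, 60))
  sp <- split_events_by_day(ev2)
  pieces <- sp[sp$activity == "stepping", ]
  expect_equal(nrow(pieces), 2)
  expect_equal(pieces$duration_s, c(1800, 1800))
  expect_equal(pieces$steps, c(30, 30))
})

test_that("per-day class totals match a brute-force clipping oracle", {
  pr <- default_track_profiles()$Nursing
  ev <- generate_event_stream(pr, n_days = 7, seed = 77)
  days <- day_records(split_events_by_day(ev))
  oracle <- oracle_day_totals(ev, 7)
  for (cls in c("sitting", "standing", "stepping", "time_in_bed")) {
    expect_equal(days[[paste0(cls, "_h")]], unname(oracle[, cls]),
                 tolerance = 1e-9)
  }
  # conservation: sum over days equals raw stream totals
  expect_equal(sum(days$total_h) * 3600, sum(ev$duration_s),
               tolerance = 1e-6)
  expect_true(all(abs(days$total_h - 24) < 1e-9))
})

test_that("sedentary bouts are maximal sitting runs terminated by any other class", {
  ev <- make_stream(c("sitting", "standing", "sitting"), c(10, 1, 10))
  expect_equal(detect_sedentary_bouts(ev), c(10, 10))

  expect_equal(detect_sedentary_bouts(make_stream("sitting", 480)), 480)

  # time in bed terminates a bout and is not sedentary time
  ev2 <- make_stream(c("sitting", "time_in_bed", "sitting"), c(20, 480, 20))
  expect_equal(detect_sedentary_bouts(ev2), c(20, 20))

  # randomized streams match the run-length oracle
  for (i in 1:25) {
    set.seed(200 + i)
    n <- 60
    acts <- sample(c("sitting", "standing", "stepping", "time_in_bed"), n,
                   replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
    ev3 <- make_stream(acts, runif(n, 1, 45))
    expect_equal(detect_sedentary_bouts(ev3),
                 oracle_bouts(ev3$activity, ev3$duration_s))
  }
})

test_that("SB-ratio bounds, hand example, and 30-min boundary behave as defined", {
  expect_equal(sb_ratio(rep(10, 12)), 1.0)
  expect_equal(sb_ratio(480), 0.0)
  expect_equal(sb_ratio(c(20, 40, 20, 100)), 40 / 180)
  # a bout of exactly 30 min is prolonged (strict < cut-off)
  expect_equal(sb_ratio(c(30, 10)), 10 / 40)
  expect_equal(sb_ratio(c(29.999, 10)), 1.0)
  expect_true(is.na(sb_ratio(numeric(0))))
})

test_that("SB-ratio moves monotonically with appended bouts", {
  bouts <- c(10, 50, 25)
  expect_lt(sb_ratio(c(bouts, 35)), sb_ratio(bouts))
  expect_gt(sb_ratio(c(bouts, 5)), sb_ratio(bouts))
})

test_that("MVPA classification follows per-event cadence at the 100 steps/min cut-point", {
  ev <- make_stream("stepping", 30, steps = 3600)  # 120 steps/min
  expect_equal(mvpa_minutes(ev), 30)
  ev2 <- make_stream("stepping", 30, steps = 2400)  # 80 steps/min
  expect_equal(mvpa_minutes(ev2), 0)
  ev3 <- make_stream("stepping", 30, steps = 3000)  # exactly 100
  expect_equal(mvpa_minutes(ev3), 30)

  # mixed synthetic day equals brute-force per-event classification
  ev4 <- generate_event_stream(default_track_profiles()$Sports, 1, seed = 5)
  steppers <- ev4[ev4$activity == "stepping", ]
  brute <- sum(steppers$duration_s[
    steppers$steps / (steppers$duration_s / 60) >= 100]) / 60
  expect_equal(mvpa_minutes(ev4), brute)
  # MVPA can never exceed stepping time
  expect_lte(mvpa_minutes(ev4), sum(steppers$duration_s) / 60)
})

test_that("guideline adherence applies the youth 'every day' and adult weekly rules", {
  expect_true(guideline_adherence(make_days(c(60, 60, 60, 60)), "youth"))
  expect_true(guideline_adherence(make_days(c(60, 60, 60, 60)), "adult"))
  expect_false(guideline_adherence(make_days(c(59, 120, 120, 120)), "youth"))
  expect_true(guideline_adherence(make_days(c(59, 120, 120, 120)), "adult"))
  # mean 21.25 min/day -> 148.75 min/week < 150
  expect_false(guideline_adherence(make_days(c(20, 20, 20, 25)), "adult"))
  expect_true(is.na(guideline_adherence(make_days(numeric(0)), "youth")))
})

test_that("participant validity needs two complete weekdays and two weekend days", {
  pr <- default_track_profiles()$Admin
  # stream starting Saturday, 3 days: 2 weekend days + 1 weekday
  ev <- generate_event_stream(pr, n_days = 3, seed = 9,
                              start_date = as.Date("2024-01-06"))
  pab <- summarize_participants(ev)
  expect_equal(pab$n_valid_weekend_days, 2)
  expect_equal(pab$n_valid_weekdays, 1)
  expect_false(pab$valid)
  expect_true(is.na(pab$adheres_youth))

  # full week starting Monday is valid
  ev7 <- generate_event_stream(pr, n_days = 7, seed = 9)
  expect_true(summarize_participants(ev7)$valid)
})

test_that("a uniform repeating stream summarizes to any single day's totals", {
  day_pattern <- list(activity = c("time_in_bed", "sitting", "standing",
                                   "stepping", "sitting"),
                      minutes = c(8 * 60, 5 * 60, 4 * 60, 2 * 60, 5 * 60),
                      steps = c(0, 0, 0, 2 * 60 * 110, 0))
  ev <- make_stream(rep(day_pattern$activity, 7),
                    rep(day_pattern$minutes, 7),
                    rep(day_pattern$steps, 7))
  pab <- summarize_participants(ev)
  expect_equal(pab$sitting_h, 10)
  expect_equal(pab$standing_h, 4)
  expect_equal(pab$stepping_h, 2)
  expect_equal(pab$time_in_bed_h, 8)
  expect_equal(pab$mvpa_min, 120)
  expect_true(pab$adheres_youth)
})

test_that("per-participant means match brute-force recomputation from raw events", {
  cohort <- generate_cohort(c(Sports = 3, Admin = 3), seed = 61)
  events <- generate_cohort_events(cohort, n_days = 7, seed = 62)
  pab <- summarize_participants(events)
  for (id in cohort$participant_id) {
    ev <- events[events$participant_id == id, ]
    oracle <- oracle_day_totals(ev, 7)
    row <- pab[pab$participant_id == id, ]
    expect_equal(row$sitting_h, mean(oracle[, "sitting"]), tolerance = 1e-9)
    expect_equal(row$stepping_h, mean(oracle[, "stepping"]), tolerance = 1e-9)
  }
})

test_that("an empty stream yields an invalid participant, not an error", {
  ev <- make_stream(character(0), numeric(0))
  pab <- summarize_participants(ev)
  expect_equal(nrow(pab), 0)
})

test_that("summaries survive a round trip through the event CSV dialect", {
  ev <- generate_event_stream(default_track_profiles()$Hairdresser, 7,
                              seed = 13)
  path <- tempfile(fileext = ".csv")
  write_events_csv(ev, path)
  back <- read_events_csv(path)
  expect_equal(summarize_participants(back)[, -1],
               summarize_participants(ev)[, -1], tolerance = 1e-9)
  unlink(path)
})

test_that("a bout crossing midnight keeps its full length for classification", {
  # 23:40-00:10 sitting (30 min unbroken bout) between standing blocks:
  # exactly 30 min, so it is prolonged on both days despite the split
  ev <- make_stream(c("standing", "sitting", "standing"),
                    c(23 * 60 + 40, 30, 24 * 60 - 50 + 24 * 60))
  sp <- split_events_by_day(ev)
  sit <- sp[sp$activity == "sitting", ]
  expect_equal(nrow(sit), 2)
  expect_true(all(sit$bout_total_min == 30))
  days <- day_records(sp)
  expect_equal(days$sedentary_short_min[1:2], c(0, 0))
  expect_equal(days$sedentary_min[1:2], c(20, 10))
})
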