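# Builders for small deterministic fixtures used across test files.

t0_utc <- function(date = "2024-01-01") {
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
}

# A contiguous event stream from (activity, duration_min, steps) triples.
make_stream <- function(activity, duration_min, steps = NULL,
                        start = t0_utc()) {
  duration_s <- duration_min * 60
  if (is.null(steps)) steps <- numeric(length(activity))
  starts <- start + cumsum(c(0, duration_s))[seq_along(duration_s)]
  data.frame(start = starts, duration_s = duration_s, activity = activity,
             steps = steps, stringsAsFactors = FALSE)
}

# A full crafted CST session: 16 practice + 64 test trials per round, with
# controllable test-trial RTs, correctness and shift/congruency flags.
make_cst_session <- function(rt_by_round = rep(500, 5),
                             n_correct = rep(64, 5),
                             round3_shift = c(FALSE, rep(TRUE, 63)),
                             congruent45 = rep(FALSE, 64)) {
  rounds <- lapply(1:5, function(r) {
    n <- 80L
    phase <- rep(c("practice", "test"), c(16L, 64L))
    rt <- rep(rt_by_round[r], n)
    correct <- rep(TRUE, n)
    test_idx <- 17:80
    if (n_correct[r] < 64) {
      correct[test_idx[seq_len(64 - n_correct[r])]] <- FALSE
    }
    is_shift <- rep(NA, n)
    if (r == 3L) is_shift[test_idx] <- round3_shift
    is_congruent <- rep(NA, n)
    if (r %in% 4:5) is_congruent[test_idx] <- congruent45
    data.frame(round = r, phase = phase, index = seq_len(n),
               task = "shape", is_shift = is_shift,
               is_congruent = is_congruent, rt_ms = rt, correct = correct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rounds)
}

# Minimal day_records-shaped table for adherence tests.
make_days <- function(mvpa, weekend = rep(FALSE, length(mvpa))) {
  data.frame(participant_id = rep("P1", length(mvpa)),
             date = as.Date("2024-01-01") + seq_along(mvpa) - 1,
             is_weekend = weekend, complete = rep(TRUE, length(mvpa)),
             mvpa_minutes = mvpa, stringsAsFactors = FALSE)
}
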