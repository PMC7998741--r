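#' Generate a synthetic color-shape test session
#'
#' Emulates a five-round color-shape session: each round has 16 practice and
#' 64 test trials. Rounds 1 (shape) and 2 (color) are single-task baselines;
#' round 3 mixes shape and color trials at random, so a test trial is a
#' shift trial iff its task differs from the preceding test trial (the first
#' test trial has no predecessor and is non-shift); rounds 4 and 5 present
#' bivalent stimuli that are congruent or incongruent with equal
#' probability. Reaction times are lognormal with mean `base_rt_ms`, plus
#' `shift_cost_ms` on shift trials and `inhibition_cost_ms` on incongruent
#' trials; anticipations (< 170 ms) and lapses (> 5000 ms) are injected at
#' `guess_rate` and `lapse_rate`; correctness is Bernoulli with
#' `1 - error_rate`.
#'
#' @param profile A [cognitive_profile()].
#' @param seed Integer seed.
#' @return Data.frame with columns `round`, `phase` (practice/test),
#'   `index`, `task`, `is_shift` (round-3 test trials, else NA),
#'   `is_congruent` (rounds 4-5, else NA), `rt_ms`, `correct`.
#' @export
generate_cst_session <- function(profile, seed) {
  stopifnot(inherits(profile, "cognitive_profile"))
  with_seed(seed, {
    rounds <- lapply(1:5, function(r) {
      n_prac <- 16L; n_test <- 64L; n <- n_prac + n_test
      phase <- rep(c("practice", "test"), c(n_prac, n_test))
      task <- switch(as.character(r),
        "1" = rep("shape", n),
        "2" = rep("color", n),
        "3" = sample(c("shape", "color"), n, replace = TRUE),
        "4" = rep("shape", n),
        "5" = rep("color", n))
      is_shift <- rep(NA, n)
      if (r == 3L) {
        tt <- which(phase == "test")
        sh <- c(FALSE, task[tt][-1L] != task[tt][-length(tt)])
        is_shift[tt] <- sh
      }
      is_congruent <- rep(NA, n)
      if (r %in% 4:5) is_congruent <- sample(c(TRUE, FALSE), n, replace = TRUE)
      mu <- rep(profile$base_rt_ms, n)
      mu <- mu + ifelse(!is.na(is_shift) & is_shift, profile$shift_cost_ms, 0)
      mu <- mu + ifelse(!is.na(is_congruent) & !is_congruent,
                        profile$inhibition_cost_ms, 0)
      sdlog <- sqrt(log(1 + profile$rt_cv^2))
      rt <- rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      u <- runif(n)
      rt[u < profile$guess_rate] <- runif(sum(u < profile$guess_rate), 50, 169)
      lap <- u >= profile$guess_rate &
        u < profile$guess_rate + profile$lapse_rate
      rt[lap] <- runif(sum(lap), 5001, 9000)
      data.frame(round = r, phase = phase, index = seq_len(n), task = task,
                 is_shift = is_shift, is_congruent = is_congruent,
                 rt_ms = rt,
                 correct = runif(n) >= profile$error_rate,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rounds)
  })
}

#' Generate a synthetic letter-memory test session
#'
#' Twelve test trials of consonant series of length 5, 7 or 9, each length
#' used four times in shuffled order. The target is the last three presented
#' letters; each is recalled correctly with probability
#' `updating_recall_prob`, otherwise replaced by `"Blank"` or by a consonant
#' outside the presented series (half/half), so the expected session score
#' is `36 * updating_recall_prob`. With probability `missing_rate` a trial
#' has no response at all (all three entries missing).
#'
#' @param profile A [cognitive_profile()].
#' @param seed Integer seed.
#' @param missing_rate Probability a trial is skipped without a response.
#' @return Data.frame with columns `trial`, `series_length`, `presented`
#'   (letters separated by `"-"`), `target1`..`target3`,
#'   `recalled1`..`recalled3` (consonant, `"Blank"`, or NA when missing).
#' @export
generate_lmt_session <- function(profile, seed, missing_rate = 0) {
  stopifnot(inherits(profile, "cognitive_profile"))
  assert_prob(missing_rate, "missing_rate")
  with_seed(seed, {
    lengths <- sample(rep(c(5L, 7L, 9L), each = 4L))
    trials <- lapply(seq_along(lengths), function(i) {
      len <- lengths[i]
      presented <- sample(.lmt_consonants, len)
      target <- presented[(len - 2L):len]
      if (runif(1) < missing_rate) {
        recalled <- rep(NA_character_, 3L)
      } else {
        recalled <- vapply(target, function(letter) {
          if (runif(1) < profile$updating_recall_prob) return(letter)
          if (runif(1) < 0.5) return("Blank")
          sample(setdiff(.lmt_consonants, presented), 1L)
        }, character(1), USE.NAMES = FALSE)
      }
      data.frame(trial = i, series_length = len,
                 presented = paste(presented, collapse = "-"),
                 target1 = target[1L], target2 = target[2L],
                 target3 = target[3L],
                 recalled1 = recalled[1L], recalled2 = recalled[2L],
                 recalled3 = recalled[3L], stringsAsFactors = FALSE)
    })
    do.call(rbind, trials)
  })
}

#' Generate cognitive test sessions for a whole cohort
#'
#' @param cohort Data.frame from [generate_cohort()].
#' @param profile A [cognitive_profile()] shared by all participants (the
#'   per-participant randomness comes from derived seeds).
#' @param seed Master seed.
#' @param lmt_missing_rate Passed to [generate_lmt_session()].
#' @return List with elements `cst` and `lmt`, each a data.frame with a
#'   `participant_id` column.
#' @export
generate_cohort_cognition <- function(cohort, profile = cognitive_profile(),
                                      seed, lmt_missing_rate = 0) {
  seeds <- derive_seeds(seed, 2L * nrow(cohort))
  cst <- lapply(seq_len(nrow(cohort)), function(i) {
    cbind(participant_id = cohort$participant_id[i],
          generate_cst_session(profile, seed = seeds[2L * i - 1L]),
          stringsAsFactors = FALSE)
  })
  lmt <- lapply(seq_len(nrow(cohort)), function(i) {
    cbind(participant_id = cohort$participant_id[i],
          generate_lmt_session(profile, seed = seeds[2L * i],
                               missing_rate = lmt_missing_rate),
          stringsAsFactors = FALSE)
  })
  list(cst = do.call(rbind, cst), lmt = do.call(rbind, lmt))
}
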