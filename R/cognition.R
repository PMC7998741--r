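#' Score the letter-memory test (updating)
#'
#' The updating score is the total number of correctly recalled letters over
#' the test trials, regardless of order: per trial, the recalled entries are
#' intersected with the three target letters as multisets (a duplicated
#' target letter must be recalled twice to count twice). `"Blank"` and
#' missing entries score zero; trials with no response at all contribute
#' zero and are counted as missing.
#'
#' @param trials Data.frame with columns `target1`..`target3` and
#'   `recalled1`..`recalled3` (see [generate_lmt_session()]); at most 12
#'   test trials.
#' @return Integer score in `[0, 3 * nrow(trials)]`, with attribute
#'   `n_missing_trials`.
#' @examples
#' tr <- data.frame(target1 = "K", target2 = "L", target3 = "M",
#'                  recalled1 = "M", recalled2 = "K", recalled3 = "L")
#' score_lmt(tr)  # 3: order does not matter
#' @export
score_lmt <- function(trials) {
  if (nrow(trials) > 12L) {
    stop("a letter-memory session has at most 12 test trials", call. = FALSE)
  }
  rec_cols <- paste0("recalled", 1:3)
  tgt_cols <- paste0("target", 1:3)
  entries <- unlist(trials[rec_cols], use.names = FALSE)
  ok <- is.na(entries) | entries == "Blank" |
    (nchar(entries) == 1L & entries %in% LETTERS)
  if (!all(ok)) {
    stop("recalled entries must be single letters, \"Blank\", or missing; ",
         "offending value(s): ",
         paste(unique(entries[!ok]), collapse = ", "), call. = FALSE)
  }
  total <- 0L
  n_missing <- 0L
  for (i in seq_len(nrow(trials))) {
    rec <- as.character(unlist(trials[i, rec_cols], use.names = FALSE))
    if (all(is.na(rec))) {
      n_missing <- n_missing + 1L
      next
    }
    rec <- rec[!is.na(rec) & rec != "Blank"]
    tgt <- as.character(unlist(trials[i, tgt_cols], use.names = FALSE))
    for (letter in unique(rec)) {
      total <- total + min(sum(rec == letter), sum(tgt == letter))
    }
  }
  structure(as.integer(total), n_missing_trials = n_missing)
}

#' Filter a color-shape test session
#'
#' Applies the reaction-time filter chain to the 5 x 64 test trials, in
#' order: (1) chance performance — a participant with any round at 32 or
#' fewer correct test answers out of 64 is excluded entirely; (2) round-3
#' trials that do not demand a task switch (two consecutive same-task
#' trials, and the round's first trial) are dropped; (3) congruent trials in
#' rounds 4-5 are dropped (they require no inhibition); (4) reaction times
#' below 170 ms or above 5000 ms are dropped (boundary values are kept);
#' (5) incorrect trials are dropped, so RT statistics use correct trials
#' only; (6) intrapersonal outliers — trials outside the per-round mean
#' +/- 3 SD of the remaining trials — are dropped in a single pass. Each
#' removal is attributed to the first rule that caught it.
#'
#' @param trials One session's trials (see [generate_cst_session()]);
#'   exactly 64 test trials per round are required.
#' @param rt_min,rt_max RT admissibility window in ms (defaults 170, 5000;
#'   strict inequalities exclude only values outside the window).
#' @param sd_multiplier Outlier width in SDs (default 3).
#' @param sd_scope `"round"` (default): outlier statistics per round;
#'   `"pooled"`: one mean/SD across rounds.
#' @param chance_cutoff A round with `<= chance_cutoff` correct test answers
#'   excludes the participant (default 32).
#' @return List of class `cst_filter`: `trials` (test trials with an
#'   `excluded_by` column, NA for survivors), `survivors`, `exclusion_log`
#'   (rule, n_removed), `excluded` (participant-level flag), `reason`.
#' @export
filter_cst <- function(trials, rt_min = 170, rt_max = 5000,
                       sd_multiplier = 3, sd_scope = c("round", "pooled"),
                       chance_cutoff = 32L) {
  sd_scope <- match.arg(sd_scope)
  tt <- trials[trials$phase == "test", , drop = FALSE]
  counts <- table(factor(tt$round, levels = 1:5))
  if (any(counts != 64L)) {
    stop("expected 64 test trials per round; got: ",
         paste(sprintf("round %s: %d", names(counts), counts),
               collapse = ", "), call. = FALSE)
  }
  tt$excluded_by <- NA_character_

  rules <- c("chance_excluded", "nonshift_excluded", "congruent_excluded",
             "rt_window_excluded", "incorrect_excluded",
             "sd_outlier_excluded")

  correct_by_round <- tapply(tt$correct, tt$round, sum)
  if (any(correct_by_round <= chance_cutoff)) {
    bad <- names(correct_by_round)[correct_by_round <= chance_cutoff]
    tt$excluded_by <- "chance_excluded"
    log <- data.frame(rule = rules,
                      n_removed = c(nrow(tt), rep(0L, length(rules) - 1L)),
                      stringsAsFactors = FALSE)
    return(structure(list(
      trials = tt, survivors = tt[0, , drop = FALSE], exclusion_log = log,
      excluded = TRUE,
      reason = sprintf("chance-level performance in round(s) %s",
                       paste(bad, collapse = ", "))
    ), class = "cst_filter"))
  }

  live <- function() is.na(tt$excluded_by)
  mark <- function(idx, rule) {
    idx <- idx[is.na(tt$excluded_by[idx])]
    tt$excluded_by[idx] <<- rule
  }
  mark(which(tt$round == 3L & !(tt$is_shift %in% TRUE)), "nonshift_excluded")
  mark(which(tt$round %in% 4:5 & tt$is_congruent %in% TRUE),
       "congruent_excluded")
  mark(which(tt$rt_ms < rt_min | tt$rt_ms > rt_max), "rt_window_excluded")
  mark(which(!tt$correct), "incorrect_excluded")
  # single-pass intrapersonal outlier filter on what remains
  if (sd_scope == "round") {
    for (r in 1:5) {
      idx <- which(live() & tt$round == r)
      if (length(idx) < 2L) next
      m <- mean(tt$rt_ms[idx]); s <- sd(tt$rt_ms[idx])
      mark(idx[abs(tt$rt_ms[idx] - m) > sd_multiplier * s],
           "sd_outlier_excluded")
    }
  } else {
    idx <- which(live())
    if (length(idx) >= 2L) {
      m <- mean(tt$rt_ms[idx]); s <- sd(tt$rt_ms[idx])
      mark(idx[abs(tt$rt_ms[idx] - m) > sd_multiplier * s],
           "sd_outlier_excluded")
    }
  }

  log <- data.frame(
    rule = rules,
    n_removed = vapply(rules, function(r)
      sum(tt$excluded_by %in% r), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(
    trials = tt, survivors = tt[live(), , drop = FALSE],
    exclusion_log = log, excluded = FALSE, reason = NA_character_
  ), class = "cst_filter")
}

#' @export
print.cst_filter <- function(x, ...) {
  cat("Color-shape test filter\n")
  if (x$excluded) {
    cat("  participant excluded:", x$reason, "\n")
  } else {
    cat(sprintf("  %d of %d test trials retained\n",
                nrow(x$survivors), nrow(x$trials)))
  }
  print(x$exclusion_log, row.names = FALSE)
  invisible(x)
}

cst_baseline_mean <- function(filtered, baseline = c("pooled", "round_means")) {
  baseline <- match.arg(baseline)
  b <- filtered$survivors[filtered$survivors$round %in% 1:2, , drop = FALSE]
  if (!nrow(b)) return(NA_real_)
  if (baseline == "pooled") {
    mean(b$rt_ms)
  } else {
    mean(tapply(b$rt_ms, b$round, mean))
  }
}

#' Shifting cost from a filtered session
#'
#' Mean RT over surviving round-3 shift trials minus the mean RT over the
#' surviving single-task trials of rounds 1-2 (pooled into one mean by
#' default).
#'
#' @param filtered A [filter_cst()] result.
#' @param baseline `"pooled"` (default) or `"round_means"` (mean of the two
#'   round means).
#' @return Cost in ms, or `NA` with a `"reason"` attribute when the
#'   participant was excluded or a required trial set is empty.
#' @export
shifting_cost <- function(filtered, baseline = c("pooled", "round_means")) {
  stopifnot(inherits(filtered, "cst_filter"))
  if (filtered$excluded) {
    return(structure(NA_real_, reason = filtered$reason))
  }
  shift <- filtered$survivors[filtered$survivors$round == 3L, , drop = FALSE]
  base <- cst_baseline_mean(filtered, baseline)
  if (!nrow(shift)) {
    return(structure(NA_real_, reason = "no surviving shift trials"))
  }
  if (is.na(base)) {
    return(structure(NA_real_, reason = "no surviving baseline trials"))
  }
  mean(shift$rt_ms) - base
}

#' Inhibition cost from a filtered session
#'
#' Mean RT over surviving incongruent trials of rounds 4-5 minus the
#' rounds-1-2 baseline mean (congruent trials were already removed by the
#' filter chain).
#'
#' @inheritParams shifting_cost
#' @return Cost in ms, or `NA` with a `"reason"` attribute.
#' @export
inhibition_cost <- function(filtered, baseline = c("pooled", "round_means")) {
  stopifnot(inherits(filtered, "cst_filter"))
  if (filtered$excluded) {
    return(structure(NA_real_, reason = filtered$reason))
  }
  inhib <- filtered$survivors[filtered$survivors$round %in% 4:5, , drop = FALSE]
  base <- cst_baseline_mean(filtered, baseline)
  if (!nrow(inhib)) {
    return(structure(NA_real_, reason = "no surviving incongruent trials"))
  }
  if (is.na(base)) {
    return(structure(NA_real_, reason = "no surviving baseline trials"))
  }
  mean(inhib$rt_ms) - base
}

#' Score cognitive test sessions for a cohort
#'
#' Runs [filter_cst()], [shifting_cost()], [inhibition_cost()] and
#' [score_lmt()] per participant.
#'
#' @param cst Color-shape trials with a `participant_id` column.
#' @param lmt Letter-memory trials with a `participant_id` column (optional).
#' @param ... Passed to [filter_cst()].
#' @return Data.frame with one row per participant: `participant_id`,
#'   `updating`, `shifting_cost_ms`, `inhibition_cost_ms`, `cst_excluded`,
#'   `note`, plus an `exclusion_log` attribute (per-participant rule
#'   counts).
#' @export
score_cognition <- function(cst, lmt = NULL, ...) {
  ids <- unique(cst$participant_id)
  logs <- list()
  rows <- lapply(ids, function(id) {
    f <- filter_cst(cst[cst$participant_id == id, , drop = FALSE], ...)
    logs[[id]] <<- cbind(participant_id = id, f$exclusion_log,
                         stringsAsFactors = FALSE)
    sc <- shifting_cost(f)
    ic <- inhibition_cost(f)
    up <- NA_integer_
    if (!is.null(lmt)) {
      lsub <- lmt[lmt$participant_id == id, , drop = FALSE]
      if (nrow(lsub)) up <- as.integer(score_lmt(lsub))
    }
    data.frame(participant_id = id, updating = up,
               shifting_cost_ms = as.numeric(sc),
               inhibition_cost_ms = as.numeric(ic),
               cst_excluded = f$excluded,
               note = if (f$excluded) f$reason else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- do.call(rbind, logs)
  out
}
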