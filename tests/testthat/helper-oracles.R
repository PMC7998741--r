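# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

# Run-length sedentary bout detector: walks the stream event by event.
oracle_bouts <- function(activity, duration_s) {
  bouts <- numeric(0)
  cur <- 0
  in_bout <- FALSE
  for (i in seq_along(activity)) {
    if (activity[i] == "sitting") {
      cur <- cur + duration_s[i]
      in_bout <- TRUE
    } else if (in_bout) {
      bouts <- c(bouts, cur)
      cur <- 0
      in_bout <- FALSE
    }
  }
  if (in_bout) bouts <- c(bouts, cur)
  bouts / 60
}

# Per-day per-class totals by clipping each raw event against day windows.
oracle_day_totals <- function(events, n_days,
                              t0 = as.POSIXct("2024-01-01", tz = "UTC")) {
  st <- as.numeric(events$start) - as.numeric(t0)
  en <- st + events$duration_s
  out <- list()
  for (d in seq_len(n_days)) {
    lo <- (d - 1) * 86400
    hi <- d * 86400
    hrs <- c(sitting = 0, standing = 0, stepping = 0, time_in_bed = 0)
    for (i in seq_along(st)) {
      ov <- max(0, min(en[i], hi) - max(st[i], lo))
      hrs[[events$activity[i]]] <- hrs[[events$activity[i]]] + ov / 3600
    }
    out[[d]] <- hrs
  }
  do.call(rbind, out)
}

# Sequential re-application of the six CST filter rules, one trial at a
# time. Returns the surviving test-trial keys ("round:index") or NULL when
# the participant is excluded for chance performance.
oracle_filter_cst <- function(trials, rt_min = 170, rt_max = 5000,
                              sd_mult = 3, chance_cutoff = 32) {
  tt <- trials[trials$phase == "test", , drop = FALSE]
  for (r in 1:5) {
    sub <- tt[tt$round == r, , drop = FALSE]
    if (sum(sub$correct) <= chance_cutoff) return(NULL)
  }
  keep <- rep(TRUE, nrow(tt))
  for (i in seq_len(nrow(tt))) {
    if (tt$round[i] == 3 && !isTRUE(tt$is_shift[i])) keep[i] <- FALSE
  }
  for (i in seq_len(nrow(tt))) {
    if (keep[i] && tt$round[i] %in% c(4, 5) && isTRUE(tt$is_congruent[i])) {
      keep[i] <- FALSE
    }
  }
  for (i in seq_len(nrow(tt))) {
    if (keep[i] && (tt$rt_ms[i] < rt_min || tt$rt_ms[i] > rt_max)) {
      keep[i] <- FALSE
    }
  }
  for (i in seq_len(nrow(tt))) {
    if (keep[i] && !tt$correct[i]) keep[i] <- FALSE
  }
  for (r in 1:5) {
    idx <- which(keep & tt$round == r)
    if (length(idx) < 2) next
    m <- mean(tt$rt_ms[idx])
    s <- sd(tt$rt_ms[idx])
    for (i in idx) {
      if (abs(tt$rt_ms[i] - m) > sd_mult * s) keep[i] <- FALSE
    }
  }
  paste(tt$round[keep], tt$index[keep], sep = ":")
}

# Kendall tau-b by explicit pair enumeration with tie corrections.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) {
        tx <- tx + 1; ty <- ty + 1
      } else if (dx == 0) {
        tx <- tx + 1
      } else if (dy == 0) {
        ty <- ty + 1
      } else if (dx == dy) {
        conc <- conc + 1
      } else {
        disc <- disc + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Classical Cohen's d from two raw samples.
oracle_d_raw <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}
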