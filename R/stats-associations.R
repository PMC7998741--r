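#' Correlation and regression suite for activity-cognition associations
#'
#' For every pair of an activity variable and a cognitive outcome, computes
#' Pearson's r, Spearman's rho and Kendall's tau-b with p-values on
#' pairwise-complete cases (per-cell n reported). Additionally fits, per
#' cognitive outcome, a linear regression on all activity variables
#' (listwise within the model) with coefficient tests.
#'
#' @param pab Data.frame of participant activity summaries (see
#'   [summarize_participants()]).
#' @param scores Data.frame of cognitive scores (see [score_cognition()]);
#'   merged on `participant_id`.
#' @param pab_vars,score_vars Column names to cross (defaults: sitting,
#'   standing, stepping hours x inhibition, shifting, updating).
#' @param alpha Significance level used for the `significant` flag.
#' @return List of class `association_suite`: `correlations` (one row per
#'   cell: n, estimates, p values, significance flags) and `regressions`
#'   (per outcome: n and coefficient table).
#' @export
association_suite <- function(pab, scores,
                              pab_vars = c("sitting_h", "standing_h",
                                           "stepping_h"),
                              score_vars = c("inhibition_cost_ms",
                                             "shifting_cost_ms", "updating"),
                              alpha = 0.05) {
  d <- merge(pab, scores, by = "participant_id")
  cells <- expand.grid(pab_var = pab_vars, score_var = score_vars,
                       stringsAsFactors = FALSE)
  cors <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    x <- d[[cells$pab_var[i]]]
    y <- d[[cells$score_var[i]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(data.frame(cells[i, ], n = n, pearson_r = NA_real_,
                        pearson_p = NA_real_, spearman_rho = NA_real_,
                        spearman_p = NA_real_, kendall_tau = NA_real_,
                        kendall_p = NA_real_, stringsAsFactors = FALSE))
    }
    pe <- cor.test(x[ok], y[ok], method = "pearson")
    sp <- suppressWarnings(cor.test(x[ok], y[ok], method = "spearman"))
    ke <- suppressWarnings(cor.test(x[ok], y[ok], method = "kendall"))
    data.frame(cells[i, ], n = n,
               pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
               spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
               kendall_tau = unname(ke$estimate), kendall_p = ke$p.value,
               stringsAsFactors = FALSE)
  }))
  cors$significant <- !is.na(cors$pearson_p) & cors$pearson_p < alpha
  regressions <- lapply(score_vars, function(sv) {
    sub <- d[, c(sv, pab_vars)]
    sub <- sub[complete.cases(sub), , drop = FALSE]
    if (nrow(sub) < length(pab_vars) + 2L) {
      return(list(outcome = sv, n = nrow(sub), coefficients = NULL))
    }
    fit <- lm(as.formula(paste(sv, "~", paste(pab_vars, collapse = " + "))),
              data = sub)
    co <- suppressWarnings(summary(fit))$coefficients
    list(outcome = sv, n = nrow(sub),
         coefficients = data.frame(term = rownames(co),
                                   estimate = co[, 1L], se = co[, 2L],
                                   t = co[, 3L], p = co[, 4L],
                                   row.names = NULL,
                                   stringsAsFactors = FALSE))
  })
  names(regressions) <- score_vars
  structure(list(correlations = cors, regressions = regressions,
                 alpha = alpha),
            class = "association_suite")
}

#' @export
print.association_suite <- function(x, ...) {
  cat("Activity-cognition association suite\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  for (r in x$regressions) {
    cat(sprintf("\nRegression of %s on activity variables (n = %d):\n",
                r$outcome, r$n))
    if (!is.null(r$coefficients)) {
      print(r$coefficients, row.names = FALSE, digits = 3)
    }
  }
  invisible(x)
}

#' Subset sensitivity analysis
#'
#' Re-runs the association suite on subsets that exclude participants with
#' each flag (medication use, learning restriction, activity restriction,
#' color blindness, age group, ...) and reports how the significance
#' pattern compares with the full-sample result. Subsets smaller than
#' `min_n` are skipped with a warning.
#'
#' @param pab,scores As in [association_suite()].
#' @param flags Data.frame with `participant_id` and one logical column per
#'   exclusion flag (`TRUE` = exclude from that subset).
#' @param min_n Minimum subset size (default 10).
#' @param ... Passed to [association_suite()].
#' @return Named list per flag: `n`, the subset's `association_suite`, and
#'   `agreement` (proportion of correlation cells whose significance call
#'   matches the full sample); skipped subsets carry `skipped = TRUE`.
#' @export
subset_sensitivity <- function(pab, scores, flags, min_n = 10L, ...) {
  full <- association_suite(pab, scores, ...)
  flag_cols <- setdiff(names(flags), "participant_id")
  out <- lapply(flag_cols, function(fc) {
    excl <- flags$participant_id[flags[[fc]] %in% TRUE]
    keep <- !pab$participant_id %in% excl
    if (sum(keep) < min_n) {
      warning(sprintf("subset '%s' has n = %d < %d; skipped",
                      fc, sum(keep), min_n), call. = FALSE)
      return(list(flag = fc, n = sum(keep), skipped = TRUE))
    }
    sub <- association_suite(pab[keep, , drop = FALSE], scores, ...)
    agree <- mean(sub$correlations$significant ==
                    full$correlations$significant)
    list(flag = fc, n = sum(keep), skipped = FALSE, suite = sub,
         agreement = agree)
  })
  names(out) <- flag_cols
  attr(out, "full") <- full
  out
}
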