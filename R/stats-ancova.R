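#' Variance-inflation-factor screen for covariates
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` from regressing each covariate on all
#' the others and flags covariates above the threshold. Used to drop one of
#' a pair of highly collinear covariates (e.g. fat and muscle percentage)
#' before adjustment.
#'
#' @param covariates Data.frame or matrix of numeric covariates (>= 2
#'   columns, more rows than columns).
#' @param threshold Flagging threshold (default 10).
#' @return Named numeric vector of VIFs (`Inf` for perfectly collinear
#'   covariates) with attribute `flagged` (character vector of names).
#' @export
vif_screen <- function(covariates, threshold = 10) {
  x <- as.data.frame(covariates)
  if (ncol(x) < 2L) stop("need at least two covariates", call. = FALSE)
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) <= ncol(x) + 1L) {
    stop("need more observations than covariates", call. = FALSE)
  }
  vifs <- vapply(names(x), function(j) {
    fit <- lm(as.formula(paste0("`", j, "` ~ .")), data = x)
    # suppress the "essentially perfect fit" chatter for collinear inputs
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  structure(vifs, flagged = names(vifs)[vifs > threshold])
}

#' Cohen's d from estimated marginal means
#'
#' Backs the pooled within-group SD out of each group's EMM standard error
#' (`s_g = SE_g * sqrt(n_g)`), pools it with `(n - 1)` weights, and returns
#' `d = (emm_a - emm_b) / s_pooled` with a 95% CI from the large-sample
#' standard error `sqrt((n_a + n_b) / (n_a n_b) + d^2 / (2 (n_a + n_b - 2)))`.
#'
#' @param emm_a,se_a,n_a Mean, standard error and size of group a.
#' @param emm_b,se_b,n_b Same for group b.
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector `c(d, ci_low, ci_high)`; all `NA` when the
#'   pooled SD is zero.
#' @export
cohens_d_adjusted <- function(emm_a, se_a, n_a, emm_b, se_b, n_b,
                              conf_level = 0.95) {
  stopifnot(n_a >= 2, n_b >= 2)
  s_a <- se_a * sqrt(n_a)
  s_b <- se_b * sqrt(n_b)
  s_pooled <- sqrt(((n_a - 1) * s_a^2 + (n_b - 1) * s_b^2) / (n_a + n_b - 2))
  if (!is.finite(s_pooled) || s_pooled <= 0) {
    return(c(d = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  d <- (emm_a - emm_b) / s_pooled
  se_d <- sqrt((n_a + n_b) / (n_a * n_b) + d^2 / (2 * (n_a + n_b - 2)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  c(d = d, ci_low = d - z * se_d, ci_high = d + z * se_d)
}

#' One-way ANCOVA with estimated marginal means
#'
#' Fits `outcome ~ group + covariates` on complete cases, reports the
#' Type III omnibus F for the group factor, estimated marginal means per
#' group (model predictions with every covariate held at its complete-case
#' grand mean, via \pkg{emmeans}), and all pairwise group comparisons with
#' Bonferroni-adjusted p values and Cohen's d with 95% CI (from
#' [cohens_d_adjusted()]). A factor-coded dichotomous covariate such as sex
#' should be supplied as a numeric 0/1 indicator so it is held at its
#' observed proportion.
#'
#' @param data Data.frame containing the variables.
#' @param outcome Name of the numeric outcome column.
#' @param group Name of the grouping column (coerced to factor; >= 2
#'   levels).
#' @param covariates Character vector of numeric covariate columns (may be
#'   empty).
#' @param alpha,alpha_borderline Significance tiers (defaults 0.05, 0.1).
#' @return Object of class `group_comparison`: `outcome_name`, `F`,
#'   `df_between`, `df_error`, `p`, `significance_tier`, `n_complete`,
#'   `n_dropped`, `emm` (group, emmean, se, n), `pairwise` (group_a,
#'   group_b, estimate, raw_p, adjusted_p, cohens_d, ci95_low, ci95_high),
#'   and the fitted `model`.
#' @export
ancova <- function(data, outcome, group, covariates = character(0),
                   alpha = 0.05, alpha_borderline = 0.1) {
  vars <- c(outcome, group, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[, vars, drop = FALSE]
  cc <- complete.cases(d)
  d <- d[cc, , drop = FALSE]
  d[[group]] <- factor(d[[group]])
  if (nlevels(d[[group]]) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  n_by_group <- table(d[[group]])
  if (any(n_by_group == 0L)) {
    stop("group(s) with no complete cases: ",
         paste(names(n_by_group)[n_by_group == 0L], collapse = ", "),
         call. = FALSE)
  }
  # zero-variance covariates carry no information and would alias the
  # intercept; dropping them makes the model collapse exactly to the
  # covariate-free ANOVA in the degenerate case
  const <- covariates[vapply(covariates, function(cv)
    sd(d[[cv]]) == 0, logical(1))]
  covariates <- setdiff(covariates, const)
  rhs <- paste(c(group, covariates), collapse = " + ")
  fml <- as.formula(paste(outcome, "~", rhs))
  # sum-to-zero contrasts so the Type III group test is well defined
  contr <- setNames(list("contr.sum"), group)
  model <- lm(fml, data = d, contrasts = contr)
  a3 <- car::Anova(model, type = 3)
  row <- match(group, rownames(a3))
  Fval <- a3[row, "F value"]
  df_b <- a3[row, "Df"]
  df_e <- a3["Residuals", "Df"]
  p <- a3[row, "Pr(>F)"]

  em <- emmeans::emmeans(model, specs = group)
  es <- as.data.frame(summary(em))
  emm_tab <- data.frame(group = as.character(es[[1L]]),
                        emmean = es$emmean, se = es$SE,
                        n = as.integer(n_by_group[as.character(es[[1L]])]),
                        stringsAsFactors = FALSE)
  pr <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise"),
                              adjust = "none"))
  labs <- strsplit(as.character(pr$contrast), " - ", fixed = TRUE)
  k <- nrow(pr)
  pw <- do.call(rbind, lapply(seq_len(k), function(i) {
    ga <- labs[[i]][1L]; gb <- labs[[i]][2L]
    ia <- match(ga, emm_tab$group); ib <- match(gb, emm_tab$group)
    dd <- cohens_d_adjusted(emm_tab$emmean[ia], emm_tab$se[ia], emm_tab$n[ia],
                            emm_tab$emmean[ib], emm_tab$se[ib], emm_tab$n[ib])
    data.frame(group_a = ga, group_b = gb, estimate = pr$estimate[i],
               raw_p = pr$p.value[i],
               adjusted_p = min(1, pr$p.value[i] * k),
               cohens_d = dd[["d"]], ci95_low = dd[["ci_low"]],
               ci95_high = dd[["ci_high"]], stringsAsFactors = FALSE)
  }))
  tier <- if (p < alpha) "significant" else if (p < alpha_borderline)
    "borderline" else "none"
  structure(list(
    outcome_name = outcome, F = Fval, df_between = df_b, df_error = df_e,
    p = p, significance_tier = tier,
    n_complete = nrow(d), n_dropped = sum(!cc),
    emm = emm_tab, pairwise = pw, model = model
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("ANCOVA for '%s': F(%d, %d) = %.2f, p = %.4g [%s]\n",
              x$outcome_name, x$df_between, x$df_error, x$F, x$p,
              x$significance_tier))
  cat(sprintf("  complete cases: %d (%d dropped)\n", x$n_complete, x$n_dropped))
  cat("Estimated marginal means:\n")
  print(x$emm, row.names = FALSE, digits = 4)
  cat("Bonferroni pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
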