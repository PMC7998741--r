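#' Pearson chi-square test of independence with per-group post-hocs
#'
#' Pearson chi-square without continuity correction on an `r x k` count
#' table (typically adherent / non-adherent by group), plus per-group
#' post-hoc comparisons from adjusted standardized residuals with Bonferroni
#' correction over the `k` groups. Pairwise 2x2 sub-tables are available as
#' an alternative post-hoc.
#'
#' @param counts Matrix of non-negative counts (rows = status, columns =
#'   groups).
#' @param posthoc `"adjusted_residuals"` (default) or `"pairwise"` (each
#'   group against the rest pooled, 2x2 tables).
#' @return List of class `adherence_test`: `chi2`, `df`, `p`, `observed`,
#'   `expected`, `posthoc` (data.frame with per-group z or chi2 and
#'   Bonferroni-adjusted p).
#' @examples
#' counts <- rbind(adherent = c(2, 1, 10, 2),
#'                 non_adherent = c(24, 23, 24, 17))
#' chi_square_independence(counts)
#' @export
chi_square_independence <- function(counts,
                                    posthoc = c("adjusted_residuals",
                                                "pairwise")) {
  posthoc <- match.arg(posthoc)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column marginal", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  k <- ncol(counts)
  groups <- colnames(counts) %||% paste0("G", seq_len(k))
  ph <- if (posthoc == "adjusted_residuals") {
    z <- ct$stdres[1L, ]
    data.frame(group = groups, z = as.numeric(z),
               adjusted_p = pmin(1, 2 * pnorm(-abs(as.numeric(z))) * k),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_len(k), function(j) {
      sub <- cbind(counts[, j], rowSums(counts[, -j, drop = FALSE]))
      cs <- suppressWarnings(chisq.test(sub, correct = FALSE))
      data.frame(group = groups[j], chi2 = unname(cs$statistic),
                 adjusted_p = min(1, cs$p.value * k),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value, observed = counts, expected = ct$expected,
                 posthoc = ph),
            class = "adherence_test")
}

#' @export
print.adherence_test <- function(x, ...) {
  cat(sprintf("Chi-square test: chi2(%d) = %.2f, p = %.4g\n",
              x$df, x$chi2, x$p))
  cat("Post-hoc (Bonferroni-adjusted):\n")
  print(x$posthoc, row.names = FALSE, digits = 4)
  invisible(x)
}

#' A-priori total sample size for a one-way ANOVA omnibus test
#'
#' Finds the smallest total `N` whose omnibus F test (df1 = k - 1,
#' df2 = N - k) reaches the target power at level `alpha` against Cohen's
#' effect size `f`, with noncentrality `lambda = f^2 N` from the noncentral
#' F distribution. By default the search follows the G*Power convention of
#' a balanced design, returning the smallest multiple of `k`;
#' `equal_groups = FALSE` searches every integer `N`.
#'
#' @param k_groups Number of groups (>= 2).
#' @param f Cohen's f effect size (> 0).
#' @param alpha Significance level.
#' @param power Target power, in `(alpha, 1)`.
#' @param equal_groups Restrict `N` to multiples of `k_groups` (default
#'   `TRUE`).
#' @return Total sample size (integer), with attribute `power` giving the
#'   achieved power.
#' @examples
#' anova_power_n(4, 0.40, 0.05, 0.80)  # 76
#' @export
anova_power_n <- function(k_groups, f, alpha = 0.05, power = 0.80,
                          equal_groups = TRUE) {
  if (k_groups < 2L) stop("`k_groups` must be >= 2", call. = FALSE)
  if (f <= 0) stop("`f` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1) {
    stop("need 0 < alpha < power < 1", call. = FALSE)
  }
  achieved <- function(N) {
    df1 <- k_groups - 1L
    df2 <- N - k_groups
    1 - pf(qf(1 - alpha, df1, df2), df1, df2, ncp = f^2 * N)
  }
  candidates <- if (equal_groups) {
    seq(2L * k_groups, 1000000L, by = k_groups)
  } else {
    seq(k_groups + 1L, 1000000L)
  }
  for (N in candidates) {
    pw <- achieved(N)
    if (pw >= power) return(structure(as.integer(N), power = pw))
  }
  stop("no feasible N below 1e6 for the requested power", call. = FALSE)
}
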