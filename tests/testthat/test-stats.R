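test_that("VIF screening quantifies multicollinearity", {
  set.seed(1)
  x <- data.frame(a = rnorm(10000), b = rnorm(10000))
  v <- vif_screen(x)
  expect_true(all(abs(v - 1) < 0.01))
  expect_length(attr(v, "flagged"), 0)

  y <- data.frame(a = x$a, b = 2 * x$a + rnorm(10000, sd = 1e-3))
  v2 <- vif_screen(y)
  expect_true(all(v2 > 10))
  expect_setequal(attr(v2, "flagged"), c("a", "b"))

  z <- data.frame(a = x$a, b = 2 * x$a)
  expect_true(all(is.infinite(vif_screen(z))))

  # two-covariate closed form: VIF = 1 / (1 - r^2)
  set.seed(2)
  fat <- rnorm(500, 28, 8)
  muscle <- 60 - 0.9 * fat + rnorm(500, sd = 2)
  r2 <- cor(fat, muscle)^2
  v3 <- vif_screen(data.frame(fat, muscle))
  expect_equal(unname(v3), rep(1 / (1 - r2), 2), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("ANCOVA reproduces the df arithmetic and degenerates to ANOVA", {
  set.seed(3)
  n <- c(26, 24, 34, 19)
  d <- data.frame(
    g = rep(c("H", "A", "S", "N"), n),
    x1 = rnorm(103), x2 = rnorm(103), x3 = rnorm(103))
  d$y <- rnorm(103, mean = rep(c(8, 10, 8, 9), n))
  res <- ancova(d, "y", "g", c("x1", "x2", "x3"))
  expect_equal(res$df_between, 3)
  expect_equal(res$df_error, 103 - 4 - 3)
  expect_equal(res$n_complete, 103)
  expect_equal(nrow(res$pairwise), 6)

  # constant covariates: F equals the one-way ANOVA F exactly
  d$z <- 1
  res0 <- ancova(d, "y", "g", "z")
  plain <- anova(lm(y ~ g, data = d))
  expect_equal(res0$F, plain$`F value`[1], tolerance = 1e-9)
  expect_equal(res0$df_error, 99)

  # covariates with zero effect: EMMs close to raw group means
  raw <- tapply(d$y, d$g, mean)
  emm <- setNames(res$emm$emmean, res$emm$group)
  expect_true(all(abs(emm[names(raw)] - raw) < 0.2))

  # EMMs weighted by group size reproduce the overall adjusted mean
  res_w <- sum(res0$emm$emmean * res0$emm$n) / sum(res0$emm$n)
  expect_equal(res_w, mean(d$y), tolerance = 1e-9)

  expect_error(ancova(d[d$g != "H", ], "y", "g", "x1"), NA)
  expect_error(ancova(d, "missing", "g"), "lacks column")
})

test_that("Bonferroni-adjusted p-values never drop below raw and cap at one", {
  set.seed(4)
  d <- data.frame(g = rep(letters[1:4], each = 20), y = rnorm(80))
  res <- ancova(d, "y", "g")
  expect_true(all(res$pairwise$adjusted_p >= res$pairwise$raw_p))
  expect_true(all(res$pairwise$adjusted_p <= 1))
})

test_that("Cohen's d from EMM summaries matches raw-data computation", {
  expect_equal(unname(cohens_d_adjusted(5, 1, 10, 5, 1, 10)["d"]), 0)
  ci <- cohens_d_adjusted(5, 1, 10, 5, 1, 10)
  expect_equal(unname(ci["ci_low"]), -unname(ci["ci_high"]))

  set.seed(5)
  a <- rnorm(34, 10, 2); b <- rnorm(24, 8, 2)
  d_emm <- cohens_d_adjusted(mean(a), sd(a) / sqrt(34), 34,
                             mean(b), sd(b) / sqrt(24), 24)
  expect_equal(unname(d_emm["d"]), oracle_d_raw(a, b), tolerance = 1e-9)

  # degenerate: zero pooled SD gives a missing marker, not an error
  expect_true(is.na(cohens_d_adjusted(5, 0, 10, 4, 0, 10)["d"]))
})

test_that("published SB-ratio effect size is reproduced from its summary statistics", {
  d <- cohens_d_adjusted(0.587, 0.020, 34, 0.468, 0.022, 24)
  expect_lt(abs(d[["d"]] - 1.06), 0.02)
  expect_lt(abs(d[["ci_low"]] - 0.51), 0.02)
  expect_lt(abs(d[["ci_high"]] - 1.61), 0.02)
})

test_that("chi-square matches the direct formula and is permutation invariant", {
  even <- rbind(c(5, 10, 15), c(10, 20, 30))
  expect_equal(chi_square_independence(even)$chi2, 0, tolerance = 1e-12)

  set.seed(6)
  for (i in 1:20) {
    tab <- matrix(rpois(8, 12) + 1, nrow = 2)
    res <- chi_square_independence(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chi2, sum((tab - expected)^2 / expected),
                 tolerance = 1e-9)
    perm <- tab[2:1, sample(4)]
    expect_equal(chi_square_independence(perm)$chi2, res$chi2,
                 tolerance = 1e-12)
  }
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))),
               "marginal")
})

test_that("noncentral-F sample size search honours conventions and bounds", {
  # balanced-design (default) reproduces the a-priori computation
  expect_equal(as.integer(anova_power_n(4, 0.40, 0.05, 0.80)), 76)
  expect_true(attr(anova_power_n(4, 0.40, 0.05, 0.80), "power") >= 0.80)

  # unconstrained search returns the smallest N with power >= target
  n_any <- as.integer(anova_power_n(4, 0.40, 0.05, 0.80,
                                    equal_groups = FALSE))
  pow <- function(N) 1 - pf(qf(0.95, 3, N - 4), 3, N - 4, ncp = 0.16 * N)
  expect_true(pow(n_any) >= 0.80 && pow(n_any - 1) < 0.80)
  expect_lte(n_any, 76)

  # minimal feasible N boundary: a barely-above-alpha target
  expect_equal(as.integer(anova_power_n(4, 2, 0.05, 0.06,
                                        equal_groups = FALSE)), 5)
  expect_error(anova_power_n(1, 0.4), ">= 2")
  expect_error(anova_power_n(4, 0.4, 0.5, 0.2), "alpha < power")
})

test_that("the returned N attains its power in a k = 2 simulation", {
  N <- as.integer(anova_power_n(2, 0.5, 0.05, 0.80, equal_groups = TRUE))
  f <- 0.5
  # two equal groups with means +/- delta/2 give Cohen's f = delta/(2 sd)
  delta <- 2 * f
  set.seed(7)
  rej <- mean(replicate(3000, {
    g <- rep(0:1, each = N / 2)
    y <- rnorm(N, mean = g * delta)
    summary(aov(y ~ factor(g)))[[1]]$`Pr(>F)`[1] < 0.05
  }))
  target <- attr(anova_power_n(2, 0.5, 0.05, 0.80), "power")
  expect_lt(abs(rej - target), 3 * sqrt(target * (1 - target) / 3000))
})

test_that("correlation suite matches closed forms and flags degeneracies", {
  pab <- data.frame(participant_id = sprintf("P%02d", 1:30),
                    sitting_h = seq(5, 12, length.out = 30),
                    standing_h = rnorm(30, 4),
                    stepping_h = rnorm(30, 2))
  scores <- data.frame(participant_id = pab$participant_id,
                       inhibition_cost_ms = pab$sitting_h,  # y = x
                       shifting_cost_ms = rnorm(30, 300),
                       updating = rep(20, 30))              # constant
  suite <- association_suite(pab, scores)
  yx <- suite$correlations[suite$correlations$pab_var == "sitting_h" &
                             suite$correlations$score_var ==
                               "inhibition_cost_ms", ]
  expect_equal(yx$pearson_r, 1, tolerance = 1e-9)
  expect_equal(yx$spearman_rho, 1, tolerance = 1e-9)
  expect_equal(yx$kendall_tau, 1, tolerance = 1e-9)
  # constant outcome: missing marker, not an error
  const <- suite$correlations[suite$correlations$score_var == "updating", ]
  expect_true(all(is.na(const$pearson_r)))
  expect_equal(unique(const$n), 30)

  # tau-b equals explicit pair enumeration (with ties)
  set.seed(8)
  x <- sample(1:5, 25, replace = TRUE)
  y <- sample(1:5, 25, replace = TRUE)
  expect_equal(unname(suppressWarnings(
    cor.test(x, y, method = "kendall")$estimate)),
    oracle_tau_b(x, y), tolerance = 1e-12)
})

test_that("subset sensitivity reruns the suite and skips tiny subsets", {
  set.seed(9)
  pab <- data.frame(participant_id = sprintf("P%02d", 1:40),
                    sitting_h = rnorm(40, 8), standing_h = rnorm(40, 4),
                    stepping_h = rnorm(40, 2))
  scores <- data.frame(participant_id = pab$participant_id,
                       inhibition_cost_ms = rnorm(40, 150),
                       shifting_cost_ms = rnorm(40, 300),
                       updating = rpois(40, 20))
  flags <- data.frame(participant_id = pab$participant_id,
                      none = FALSE,
                      nearly_all = c(rep(TRUE, 35), rep(FALSE, 5)))
  expect_warning(subset_sensitivity(pab, scores, flags), "skipped")
  res <- suppressWarnings(subset_sensitivity(pab, scores, flags))
  expect_false(res$none$skipped)
  expect_equal(res$none$n, 40)
  expect_identical(res$none$suite$correlations,
                   attr(res, "full")$correlations)
  expect_true(res$nearly_all$skipped)
})

test_that("flagging 10% at random under the null rarely changes conclusions", {
  set.seed(10)
  n_rep <- 50
  stable <- vapply(seq_len(n_rep), function(i) {
    pab <- data.frame(participant_id = sprintf("P%02d", 1:60),
                      sitting_h = rnorm(60, 8), standing_h = rnorm(60, 4),
                      stepping_h = rnorm(60, 2))
    scores <- data.frame(participant_id = pab$participant_id,
                         inhibition_cost_ms = rnorm(60, 150),
                         shifting_cost_ms = rnorm(60, 300),
                         updating = rnorm(60, 20))
    full <- association_suite(pab, scores)
    keep <- runif(60) > 0.1
    sub <- association_suite(pab[keep, ], scores)
    # conclusion: no systematic association (at most 2 of 9 cells nominal)
    concl <- function(s) sum(s$correlations$significant) <= 2
    concl(full) == concl(sub)
  }, logical(1))
  expect_gte(mean(stable), 0.95)
})
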