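#' Build a study run configuration
#'
#' Collects every tunable constant of the pipeline in one object. The
#' defaults are the study constants: 30-min sedentary bout cut-off,
#' 100 steps/min MVPA cadence, 170-5000 ms reaction-time window, 3-SD
#' intrapersonal outlier filter, and significance tiers 0.05 / 0.1
#' (borderline). Overriding any of them is echoed in the run manifest.
#'
#' @param seed Master seed for all generators.
#' @param n_per_track Named counts per track (defaults to the cohort's
#'   group sizes: Hairdresser 26, Admin 24, Sports 34, Nursing 19).
#' @param n_days Days of accelerometer wear (default 7).
#' @param profiles Track profiles (default [default_track_profiles()]).
#' @param cognitive A [cognitive_profile()].
#' @param bout_cutoff_min,cadence_threshold,rt_window,sd_multiplier
#'   Processing constants.
#' @param alpha,alpha_borderline Significance tiers.
#' @param covariates Covariates offered to adjustment before VIF screening.
#' @param vif_threshold Covariate exclusion threshold (default 10).
#' @param start_date First wear day.
#' @param out_dir Optional output directory for per-stage artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_per_track = c(Hairdresser = 26L, Admin = 24L,
                                       Sports = 34L, Nursing = 19L),
                       n_days = 7L,
                       profiles = default_track_profiles(),
                       cognitive = cognitive_profile(),
                       bout_cutoff_min = 30,
                       cadence_threshold = 100,
                       rt_window = c(170, 5000),
                       sd_multiplier = 3,
                       alpha = 0.05,
                       alpha_borderline = 0.1,
                       covariates = c("age", "female", "fat_pct",
                                      "muscle_pct"),
                       vif_threshold = 10,
                       start_date = as.Date("2024-01-01"),
                       out_dir = NULL) {
  stopifnot(length(rt_window) == 2L, rt_window[1L] < rt_window[2L])
  cfg <- list(seed = as.integer(seed), n_per_track = n_per_track,
              n_days = n_days, profiles = profiles, cognitive = cognitive,
              bout_cutoff_min = bout_cutoff_min,
              cadence_threshold = cadence_threshold, rt_window = rt_window,
              sd_multiplier = sd_multiplier, alpha = alpha,
              alpha_borderline = alpha_borderline, covariates = covariates,
              vif_threshold = vif_threshold,
              start_date = as.Date(start_date), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic study pipeline
#'
#' Executes generation, accelerometry processing, cognitive scoring and the
#' statistical layer end to end: cohort and event-stream generation,
#' per-participant activity summaries, VIF covariate screening, ANCOVA with
#' estimated marginal means and Bonferroni pairwise effect sizes for each
#' activity outcome and the SB-ratio, chi-square tests on guideline
#' adherence, the activity-cognition association suite, and an attrition
#' account. With `config$out_dir` set, per-stage CSV artifacts, a JSON
#' results bundle and a provenance manifest are written; a second run with
#' the same config reproduces them byte for byte.
#'
#' @param config A [run_config()].
#' @return List of class `study_results` with elements `config`, `cohort`,
#'   `pab`, `scores`, `vif`, `ancova` (one `group_comparison` per outcome),
#'   `adherence`, `associations`, `attrition`, `manifest`.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- derive_seeds(config$seed, 3L)

  cohort <- generate_cohort(config$n_per_track, config$profiles,
                            seed = seeds[1L])
  events <- generate_cohort_events(cohort, config$profiles,
                                   n_days = config$n_days, seed = seeds[2L],
                                   start_date = config$start_date)
  pab <- summarize_participants(
    events, bout_cutoff_min = config$bout_cutoff_min,
    cadence_threshold = config$cadence_threshold)

  cog <- generate_cohort_cognition(cohort, config$cognitive, seed = seeds[3L])
  scores <- score_cognition(cog$cst, cog$lmt,
                            rt_min = config$rt_window[1L],
                            rt_max = config$rt_window[2L],
                            sd_multiplier = config$sd_multiplier)

  analysis <- analyze_study(cohort, pab, scores,
                            covariates = config$covariates,
                            vif_threshold = config$vif_threshold,
                            alpha = config$alpha,
                            alpha_borderline = config$alpha_borderline)

  attrition <- data.frame(
    stage = c("generated", "valid_pab", "cst_scored", "analyzable"),
    n = c(nrow(cohort), sum(pab$valid), sum(!scores$cst_excluded),
          sum(pab$valid & !scores$cst_excluded[
            match(pab$participant_id, scores$participant_id)])),
    stringsAsFactors = FALSE
  )

  res <- c(list(config = config, cohort = cohort, pab = pab,
                scores = scores, attrition = attrition),
           analysis)
  res$manifest <- build_manifest(config, res)
  class(res) <- "study_results"
  if (!is.null(config$out_dir)) write_study_artifacts(res, config$out_dir)
  res
}

#' Statistical layer over prepared study tables
#'
#' The analysis half of [run_study()], usable on its own tables (e.g. read
#' back from the per-stage CSVs): VIF screening with data-driven covariate
#' exclusion, ANCOVA per activity outcome, chi-square adherence tests, and
#' the association suite on valid participants.
#'
#' @param cohort,pab,scores Tables as produced by the generation stages.
#' @param covariates Candidate covariate columns in `cohort`.
#' @param vif_threshold,alpha,alpha_borderline See [run_config()].
#' @return List with `vif`, `covariates_used`, `ancova`, `adherence`,
#'   `associations`.
#' @export
analyze_study <- function(cohort, pab, scores,
                          covariates = c("age", "female", "fat_pct",
                                         "muscle_pct"),
                          vif_threshold = 10,
                          alpha = 0.05, alpha_borderline = 0.1) {
  dat <- merge(cohort, pab, by = "participant_id")
  dat <- dat[dat$valid, , drop = FALSE]

  vif <- vif_screen(dat[, covariates, drop = FALSE],
                    threshold = vif_threshold)
  flagged <- attr(vif, "flagged")
  # drop flagged covariates one group at a time, keeping the least inflated
  covs_used <- covariates
  while (length(attr(vif_screen(dat[, covs_used, drop = FALSE],
                                threshold = vif_threshold), "flagged")) > 0 &&
         length(covs_used) > 2L) {
    v <- vif_screen(dat[, covs_used, drop = FALSE],
                    threshold = vif_threshold)
    covs_used <- setdiff(covs_used, names(which.max(v)))
  }

  outcomes <- c("sitting_h", "standing_h", "stepping_h", "time_in_bed_h",
                "sb_ratio")
  anc <- lapply(setNames(outcomes, outcomes), function(oc) {
    ancova(dat, oc, "track", covs_used,
           alpha = alpha, alpha_borderline = alpha_borderline)
  })

  adh_counts <- table(
    factor(ifelse(dat$adheres_youth, "adherent", "non_adherent"),
           levels = c("adherent", "non_adherent")),
    dat$track)
  adherence <- if (all(colSums(adh_counts) > 0) &&
                   all(rowSums(adh_counts) > 0)) {
    chi_square_independence(as.matrix(adh_counts))
  } else {
    NULL
  }

  associations <- association_suite(dat, scores, alpha = alpha)

  list(vif = vif, covariates_used = covs_used, ancova = anc,
       adherence = adherence, associations = associations)
}

build_manifest <- function(config, res) {
  cfg_str <- paste(deparse(config[setdiff(names(config), "out_dir")]),
                   collapse = "")
  list(
    config_hash = content_hash(cfg_str),
    seed = config$seed,
    n_participants = nrow(res$cohort),
    n_valid = sum(res$pab$valid),
    n_cst_excluded = sum(res$scores$cst_excluded),
    covariates_used = res$covariates_used,
    stage_rows = list(cohort = nrow(res$cohort), pab = nrow(res$pab),
                      scores = nrow(res$scores))
  )
}

write_study_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  write.csv(res$pab, file.path(out_dir, "pab.csv"), row.names = FALSE)
  write.csv(res$scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  write.csv(res$attrition, file.path(out_dir, "attrition.csv"),
            row.names = FALSE)
  bundle <- list(
    manifest = res$manifest,
    vif = as.list(res$vif),
    covariates_used = res$covariates_used,
    ancova = lapply(res$ancova, function(a)
      a[c("outcome_name", "F", "df_between", "df_error", "p",
          "significance_tier", "n_complete", "emm", "pairwise")]),
    adherence = if (!is.null(res$adherence))
      res$adherence[c("chi2", "df", "p", "posthoc")],
    correlations = res$associations$correlations
  )
  jsonlite::write_json(bundle, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.study_results <- function(x, ...) {
  cat("Synthetic study run (seed", x$config$seed, ")\n")
  print(x$attrition, row.names = FALSE)
  cat("\nCovariates used after VIF screening:",
      paste(x$covariates_used, collapse = ", "), "\n\n")
  for (a in x$ancova) {
    cat(sprintf("%-14s F(%d, %d) = %6.2f, p = %.4g [%s]\n",
                a$outcome_name, a$df_between, a$df_error, a$F, a$p,
                a$significance_tier))
  }
  if (!is.null(x$adherence)) {
    cat(sprintf("\nYouth-guideline adherence: chi2(%d) = %.2f, p = %.4g\n",
                x$adherence$df, x$adherence$chi2, x$adherence$p))
  }
  n_sig <- sum(x$associations$correlations$significant, na.rm = TRUE)
  cat(sprintf("\nAssociation suite: %d of %d cells significant at alpha = %g\n",
              n_sig, nrow(x$associations$correlations),
              x$associations$alpha))
  invisible(x)
}
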