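#' Write and read posture event streams as CSV
#'
#' The event CSV dialect has one row per event with columns
#' `participant_id`, `start` (ISO-8601, UTC), `duration_s`, `activity`
#' (`sitting`, `standing`, `stepping`, `time_in_bed`) and `steps`.
#' Timestamps are written with microsecond precision so a round trip
#' through the file preserves downstream summaries.
#'
#' @param events Event data.frame (with or without `participant_id`).
#' @param path File path.
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` returns the validated event data.frame.
#' @export
write_events_csv <- function(events, path) {
  out <- events
  if (!"participant_id" %in% names(out)) out$participant_id <- "P1"
  out$start <- format(out$start, "%Y-%m-%dT%H:%M:%OS6Z", tz = "UTC")
  write.csv(out[, c("participant_id", "start", "duration_s", "activity",
                    "steps")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  raw$start <- as.POSIXct(raw$start, format = "%Y-%m-%dT%H:%M:%OS",
                          tz = "UTC")
  # microsecond-precision timestamps round on write; allow that much slack
  validate_event_stream(raw, tol = 1e-3)
  raw
}

#' Read a run configuration from JSON or YAML
#'
#' The configuration schema mirrors [run_config()]: any subset of its
#' arguments may appear as top-level keys; omitted keys take the defaults.
#' `n_per_track` is a named map track -> count; `profiles` may override the
#' default track profiles field by field.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$n_per_track)) cfg$n_per_track <- unlist(cfg$n_per_track)
  if (!is.null(cfg$profiles)) {
    defaults <- default_track_profiles()
    cfg$profiles <- lapply(setNames(names(cfg$profiles),
                                    names(cfg$profiles)), function(tr) {
      base <- defaults[[tr]]
      if (is.null(base)) stop("unknown track in config: ", tr, call. = FALSE)
      ov <- cfg$profiles[[tr]]
      track_profile(
        tr,
        target_daily_hours = unlist(ov$target_daily_hours) %||%
          base$target_daily_hours,
        mean_bout_minutes = unlist(ov$mean_bout_minutes) %||%
          base$mean_bout_minutes,
        mvpa_fraction_of_stepping = ov$mvpa_fraction_of_stepping %||%
          base$mvpa_fraction_of_stepping,
        covariate_params = utils::modifyList(base$covariate_params,
                                             ov$covariate_params %||% list())
      )
    })
  }
  if (!is.null(cfg$cognitive)) {
    cfg$cognitive <- do.call(cognitive_profile, cfg$cognitive)
  }
  do.call(run_config, cfg)
}
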