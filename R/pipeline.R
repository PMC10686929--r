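#' Run the full estimation pipeline on files
#'
#' End-to-end: ingest and validate the three input files, apply the
#' missing-year exclusion rule, estimate every retained (indicator, province)
#' pair, aggregate, and render report tables plus a machine-readable run
#' manifest (`manifest.json`: package version, configuration, input MD5
#' checksums, stage counts) under `out_dir`. On error, files created by the
#' failed run are removed.
#'
#' @param observations_path,registry_path,roster_path input CSV paths.
#' @param out_dir output directory.
#' @param config an [estimator_config()].
#' @param calendar a [phase_calendar()].
#' @param format report format, `"csv"` or `"md"`.
#' @return (invisibly) a list with `estimates`, `summary`, `exclusion`,
#'   `files`.
#' @export
run_estimate <- function(observations_path, registry_path, roster_path, out_dir,
                         config = estimator_config(),
                         calendar = phase_calendar(),
                         format = "csv") {
  for (p in c(observations_path, registry_path, roster_path)) {
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  result <- tryCatch({
    registry <- read_indicator_registry(registry_path)
    roster <- read_zone_roster(roster_path)
    observations <- read_observations(observations_path, registry, roster, calendar)
    if (nrow(observations) == 0) abort("no observations after ingest")
    exclusion <- missing_year_exclusion(observations, registry, roster, calendar)
    estimates <- estimate_impacts(observations, registry, roster, calendar,
                                  config, exclusion = exclusion)
    summary <- summarize_impacts(estimates, registry)
    written <- render_tables(estimates, summary, out_dir, format)
    manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(list(
      tool = "ddimpact", version = as.character(utils::packageVersion("ddimpact")),
      command = "estimate",
      inputs = list(
        observations = unname(tools::md5sum(observations_path)),
        registry = unname(tools::md5sum(registry_path)),
        roster = unname(tools::md5sum(roster_path))
      ),
      config = unclass(config),
      counts = list(
        rows_read = ingest_report(observations)$n_rows_read,
        rows_rejected = ingest_report(observations)$n_rows_rejected,
        pairs_excluded = sum(exclusion$excluded),
        pairs_estimated = nrow(estimates)
      ),
      format = format
    ), manifest, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, manifest)
    list(estimates = estimates, summary = summary, exclusion = exclusion,
         files = written)
  }, error = function(e) {
    unlink(written)
    abort(conditionMessage(e))
  })
  invisible(result)
}

#' Simulate a panel and write it in the pipeline's file formats
#'
#' Writes `observations.csv`, `registry.csv`, `roster.csv` and `truth.csv`
#' (the injected percent impact per indicator) plus `manifest.json` under
#' `out_dir`. Repeated invocation with the same seed is byte-identical.
#'
#' @param config a [synthetic_config()].
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @return (invisibly) character vector of files written.
#' @export
run_simulate <- function(config = synthetic_config(), seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_panel(config, seed = seed)
  f_obs <- file.path(out_dir, "observations.csv")
  write_observations(panel$observations, f_obs)
  f_reg <- file.path(out_dir, "registry.csv")
  readr::write_csv(
    panel$registry |>
      mutate(provinces = purrr::map_chr(.data$provinces, paste, collapse = ";")),
    f_reg
  )
  f_ros <- file.path(out_dir, "roster.csv")
  readr::write_csv(panel$roster, f_ros)
  f_truth <- file.path(out_dir, "truth.csv")
  readr::write_csv(panel$truth, f_truth)
  f_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    tool = "ddimpact", version = as.character(utils::packageVersion("ddimpact")),
    command = "simulate", seed = seed,
    provinces = config$provinces,
    indicators = config$indicators
  ), f_man, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(f_obs, f_reg, f_ros, f_truth, f_man))
}

#' Re-render report tables from an estimates file
#'
#' @param estimates_path path to an `estimates.csv` written by
#'   [run_estimate()] (or [render_tables()]).
#' @param out_dir output directory.
#' @param format `"csv"` or `"md"`.
#' @return (invisibly) character vector of files written.
#' @export
run_report <- function(estimates_path, out_dir, format = "md") {
  if (!file.exists(estimates_path)) {
    abort(sprintf("estimates file not found: %s", estimates_path))
  }
  estimates <- readr::read_csv(estimates_path, show_col_types = FALSE)
  assert_columns(estimates, c("indicator_id", "province", "domain",
                              "classification"), "estimates file")
  summary <- summarize_impacts(estimates)
  invisible(render_tables(estimates, summary, out_dir, format))
}
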