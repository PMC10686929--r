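#' Read a monthly observation panel
#'
#' Reads a long-format CSV of monthly zone-level indicator values with header
#' `zone_id,indicator_id,year,month,value`. An empty `value` field denotes a
#' missing report and is kept as an explicitly missing observation. Rows are
#' rejected (not fatal) when they reference a zone or indicator absent from
#' the roster/registry, when the month is malformed or outside the calendar
#' span, or when the value is negative or non-numeric; each rejection is
#' recorded with its reason in the attached ingest report.
#'
#' @param path path to the observations CSV.
#' @param registry registry tibble ([read_indicator_registry()]).
#' @param roster roster tibble ([read_zone_roster()]).
#' @param calendar a [phase_calendar()] giving the admissible month span.
#' @return a tibble with columns `zone_id`, `indicator_id`, `month` (`Date`),
#'   `value` (`NA` when missing) and `is_missing`, with the ingest report
#'   attached as attribute `"ingest_report"` (see [ingest_report()]).
#' @export
read_observations <- function(path, registry, roster, calendar = phase_calendar()) {
  if (!file.exists(path)) abort(sprintf("observations file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  assert_columns(raw, c("zone_id", "indicator_id", "year", "month", "value"),
                 "observations file")
  span <- calendar_span(calendar)
  year_n <- suppressWarnings(as.integer(raw$year))
  month_n <- suppressWarnings(as.integer(raw$month))
  value_chr <- trimws(ifelse(is.na(raw$value), "", raw$value))
  value_n <- suppressWarnings(as.numeric(ifelse(value_chr == "", NA, value_chr)))

  month_ok <- !is.na(year_n) & !is.na(month_n) & month_n >= 1 & month_n <= 12
  month_date <- rep(as.Date(NA), nrow(raw))
  month_date[month_ok] <- make_month(year_n[month_ok], month_n[month_ok])

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(reason) & !(raw$zone_id %in% roster$zone_id)] <- "unknown zone"
  reason[is.na(reason) & !(raw$indicator_id %in% registry$indicator_id)] <- "unknown indicator"
  reason[is.na(reason) & !month_ok] <- "malformed month"
  reason[is.na(reason) & (month_date < span[1] | month_date > span[2])] <- "month outside study span"
  reason[is.na(reason) & value_chr != "" & is.na(value_n)] <- "non-numeric value"
  reason[is.na(reason) & !is.na(value_n) & value_n < 0] <- "negative value"
  reason[is.na(reason) & !is.na(value_n) & !is.finite(value_n)] <- "non-finite value"

  keep <- is.na(reason)
  obs <- tibble(
    zone_id = raw$zone_id[keep],
    indicator_id = raw$indicator_id[keep],
    month = month_date[keep],
    value = value_n[keep],
    is_missing = is.na(value_n[keep])
  )
  report <- structure(list(
    n_rows_read = nrow(raw),
    n_rows_rejected = sum(!keep),
    rejected = tibble(row = which(!keep), reason = reason[!keep]),
    warnings = character()
  ), class = "ingest_report")
  if (report$n_rows_rejected > 0) {
    warn(sprintf("%d of %d observation rows rejected (see ingest_report())",
                 report$n_rows_rejected, report$n_rows_read))
  }
  attr(obs, "ingest_report") <- report
  obs
}

#' Retrieve the ingest report attached to an observation tibble
#'
#' @param observations the result of [read_observations()].
#' @return the `ingest_report` object (row counts, per-row rejection reasons).
#' @export
ingest_report <- function(observations) {
  attr(observations, "ingest_report")
}

#' @export
print.ingest_report <- function(x, ...) {
  cat("Ingest:", x$n_rows_read, "rows read,", x$n_rows_rejected, "rejected\n")
  if (x$n_rows_rejected > 0) print(count(x$rejected, .data$reason, name = "n"))
  invisible(x)
}

#' Write an observation panel
#'
#' Inverse of [read_observations()]: writes the documented CSV schema
#' (`zone_id,indicator_id,year,month,value`, empty value field for missing).
#'
#' @param observations observation tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  out <- observations |>
    mutate(
      year = as.integer(format(.data$month, "%Y")),
      month = as.integer(format(.data$month, "%m")),
      value = if_else(.data$is_missing, NA_real_, .data$value)
    ) |>
    select("zone_id", "indicator_id", "year", "month", "value")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Apply the missing-year exclusion rule
#'
#' An (indicator, province) pair is excluded from analysis when it has too
#' many fully missing calendar years. Under the default `rule = "years"`, a
#' calendar year counts as missing when no month of that year inside the
#' study span has a present value in either arm of that province, and a pair
#' is excluded when it has more than `max_missing_years` such years (so
#' exactly 2 missing years is still retained). The stricter `rule = "months"`
#' excludes on more than `max_missing_months` missing zone-free months
#' instead.
#'
#' @param observations observation tibble ([read_observations()] or
#'   [simulate_panel()]).
#' @param registry registry tibble; defines the candidate (indicator,
#'   province) pairs.
#' @param roster roster tibble; maps zones to provinces.
#' @param calendar a [phase_calendar()].
#' @param max_missing_years exclusion threshold for `rule = "years"`
#'   (default 2, i.e. "more than 2 years missing" excludes).
#' @param rule `"years"` (default) or `"months"`.
#' @param max_missing_months exclusion threshold for `rule = "months"`
#'   (default 24).
#' @return a tibble with one row per (indicator, province) pair: columns
#'   `indicator_id`, `province`, `n_missing_years`, `n_missing_months`,
#'   `excluded` (logical) and `reason` (`NA` for retained pairs).
#' @export
missing_year_exclusion <- function(observations, registry, roster,
                                   calendar = phase_calendar(),
                                   max_missing_years = 2,
                                   rule = c("years", "months"),
                                   max_missing_months = 24) {
  rule <- match.arg(rule)
  months <- phase_months(calendar)
  pairs <- registry_pairs(registry) |> select("indicator_id", "province")
  present <- observations |>
    filter(!.data$is_missing) |>
    inner_join(roster, by = "zone_id") |>
    distinct(.data$indicator_id, .data$province, .data$month)

  # grid of study months per pair, marked present where any zone reported
  grid <- tidyr::crossing(pairs, month = months$month) |>
    left_join(present |> mutate(present = TRUE),
              by = c("indicator_id", "province", "month")) |>
    mutate(
      present = !is.na(.data$present),
      year = as.integer(format(.data$month, "%Y"))
    )
  by_year <- grid |>
    group_by(.data$indicator_id, .data$province, .data$year) |>
    summarise(year_missing = !any(.data$present), .groups = "drop_last") |>
    summarise(n_missing_years = sum(.data$year_missing), .groups = "drop")
  by_month <- grid |>
    group_by(.data$indicator_id, .data$province) |>
    summarise(n_missing_months = sum(!.data$present), .groups = "drop")

  out <- pairs |>
    left_join(by_year, by = c("indicator_id", "province")) |>
    left_join(by_month, by = c("indicator_id", "province"))
  out$excluded <- if (rule == "years") {
    out$n_missing_years > max_missing_years
  } else {
    out$n_missing_months > max_missing_months
  }
  out$reason <- if_else(
    out$excluded,
    if (rule == "years") {
      sprintf("more than %d fully missing calendar years", max_missing_years)
    } else {
      sprintf("more than %d missing months", max_missing_months)
    },
    NA_character_
  )
  out
}
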