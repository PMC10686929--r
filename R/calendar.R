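#' Study phase calendar
#'
#' The controlled longitudinal design partitions the study span into five
#' named phases: a pre-program year (`T_BEFORE`), the program's first
#' (baseline) year (`T_BASELINE`), and three program periods (`T_PRODS1`,
#' `T_PRODS2`, `T_PRODS3`). The "before" mean of an indicator pools
#' `T_BEFORE` and `T_BASELINE`; the "since" mean pools the three program
#' periods.
#'
#' Defaults reproduce the evaluation design this package ships reference
#' tables for: 2016-01..2016-12, 2017-01..2017-12, 2018-01..2020-12,
#' 2021-01..2021-09 and 2021-10..2022-03 (75 months in total).
#'
#' @param phases a data frame with columns `phase_id`, `first_month`,
#'   `last_month` (months given as `Date`s or `"YYYY-MM"` strings). Phases
#'   must be non-overlapping and strictly increasing.
#' @return a tibble of class `phase_calendar` with columns `phase_id`,
#'   `first_month`, `last_month` (first-of-month `Date`s) and `period`
#'   (`"before"` or `"since"`).
#' @export
#' @examples
#' phase_calendar()
phase_calendar <- function(phases = NULL) {
  if (is.null(phases)) {
    phases <- tibble(
      phase_id = c("T_BEFORE", "T_BASELINE", "T_PRODS1", "T_PRODS2", "T_PRODS3"),
      first_month = c("2016-01", "2017-01", "2018-01", "2021-01", "2021-10"),
      last_month = c("2016-12", "2017-12", "2020-12", "2021-09", "2022-03")
    )
  }
  phases <- as_tibble(phases)
  assert_columns(phases, c("phase_id", "first_month", "last_month"), "phase calendar")
  cal <- phases |>
    mutate(
      phase_id = as.character(.data$phase_id),
      first_month = parse_month(.data$first_month),
      last_month = parse_month(.data$last_month)
    )
  if (anyDuplicated(cal$phase_id)) abort("duplicate phase_id in calendar")
  if (any(cal$first_month > cal$last_month)) {
    abort("phase first_month must not be after last_month")
  }
  if (is.unsorted(cal$first_month, strictly = TRUE) ||
      any(cal$first_month[-1] <= cal$last_month[-nrow(cal)])) {
    abort("phases must be non-overlapping and in increasing chronological order")
  }
  cal$period <- if_else(cal$phase_id %in% c("T_BEFORE", "T_BASELINE"), "before", "since")
  class(cal) <- c("phase_calendar", class(cal))
  cal
}

parse_month <- function(x) {
  if (inherits(x, "Date")) return(month_floor(x))
  x <- as.character(x)
  out <- ifelse(grepl("^\\d{4}-\\d{2}$", x), paste0(x, "-01"), x)
  out <- tryCatch(as.Date(out), error = function(e) as.Date(NA))
  if (anyNA(out)) abort("months must be Dates or 'YYYY-MM' strings")
  month_floor(out)
}

#' Enumerate the months of a phase calendar
#'
#' Expands a [phase_calendar()] into one row per calendar month, tagged with
#' its phase and with the before/since period the phase belongs to.
#'
#' @param calendar a [phase_calendar()].
#' @return a tibble with columns `month` (`Date`), `phase_id`, `period`.
#' @export
#' @examples
#' nrow(phase_months(phase_calendar())) # 75 months
phase_months <- function(calendar = phase_calendar()) {
  calendar |>
    as_tibble() |>
    mutate(month = purrr::map2(.data$first_month, .data$last_month, month_seq)) |>
    select("phase_id", "period", "month") |>
    tidyr::unnest("month") |>
    select("month", "phase_id", "period")
}

#' Overall span of a phase calendar
#'
#' @param calendar a [phase_calendar()].
#' @return a length-2 `Date` vector: first and last month of the span.
#' @export
calendar_span <- function(calendar = phase_calendar()) {
  c(min(calendar$first_month), max(calendar$last_month))
}
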