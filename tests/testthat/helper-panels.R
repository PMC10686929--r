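# Shared builders for small in-memory panels and the brute-force oracle.

mini_roster <- function(n_pro = 1, n_non = 1, province = "KONGO_CENTRAL") {
  tibble::tibble(
    zone_id = c(sprintf("pro_%d", seq_len(n_pro)), sprintf("non_%d", seq_len(n_non))),
    province = province,
    arm = rep(c("PRO_DS", "NON_PRO_DS"), c(n_pro, n_non))
  )
}

mini_registry <- function(ids = "ind1", polarity = "HIGHER_BETTER",
                          domain = "SERVICE_USE",
                          provinces = list(c("KONGO_CENTRAL"))) {
  tibble::tibble(
    indicator_id = ids, label = ids, domain = domain,
    polarity = polarity, provinces = provinces, value_kind = "rate"
  )
}

# long panel from a named list zone -> numeric vector over `months`
panel_from_values <- function(values_by_zone, months, indicator = "ind1") {
  purrr::imap(values_by_zone, function(v, z) {
    tibble::tibble(
      zone_id = z, indicator_id = indicator, month = months[seq_along(v)],
      value = v, is_missing = is.na(v)
    )
  }) |> purrr::list_rbind()
}

# random panel over a small ad-hoc calendar; used by oracle/property tests
random_panel <- function(n_pro = 2, n_non = 2, n_before = 4, n_since = 6) {
  months <- month_seq_test("2016-01-01", n_before + n_since)
  cal <- phase_calendar(tibble::tibble(
    phase_id = c("T_BEFORE", "T_BASELINE", "T_PRODS1", "T_PRODS2", "T_PRODS3"),
    first_month = months[c(1, 2, n_before + 1, n_before + 2, n_before + 3)],
    last_month = c(months[1], months[n_before],
                   months[n_before + 1], months[n_before + 2],
                   months[n_before + n_since])
  ))
  roster <- mini_roster(n_pro, n_non)
  obs <- tidyr::crossing(zone_id = roster$zone_id, month = months) |>
    dplyr::mutate(
      indicator_id = "ind1",
      value = stats::runif(dplyr::n(), 1, 20),
      is_missing = stats::runif(dplyr::n()) < 0.1,
      value = ifelse(is_missing, NA_real_, value)
    )
  list(observations = obs, roster = roster, calendar = cal,
       registry = mini_registry())
}

month_seq_test <- function(from, n) {
  seq(as.Date(from), by = "month", length.out = n)
}

# Independent brute-force recomputation of the estimator: explicit loops over
# zones and months, no vectorisation, no shared code with the package.
oracle_percent_impact <- function(observations, roster, calendar,
                                  before = c("T_BEFORE", "T_BASELINE"),
                                  since = c("T_PRODS1", "T_PRODS2", "T_PRODS3")) {
  phase_of <- list()
  for (i in seq_len(nrow(calendar))) {
    ms <- seq(calendar$first_month[i], calendar$last_month[i], by = "month")
    for (m in as.character(ms)) phase_of[[m]] <- calendar$phase_id[i]
  }
  arm_of <- list()
  for (i in seq_len(nrow(roster))) arm_of[[roster$zone_id[i]]] <- roster$arm[i]
  sums <- list()
  ns <- list()
  for (i in seq_len(nrow(observations))) {
    if (isTRUE(observations$is_missing[i])) next
    ph <- phase_of[[as.character(observations$month[i])]]
    if (is.null(ph)) next
    period <- if (ph %in% before) "before" else if (ph %in% since) "since" else next
    key <- paste(arm_of[[observations$zone_id[i]]], period)
    sums[[key]] <- (sums[[key]] %||% 0) + observations$value[i]
    ns[[key]] <- (ns[[key]] %||% 0) + 1
  }
  m <- function(key) if (is.null(ns[[key]])) NA_real_ else sums[[key]] / ns[[key]]
  d_pro <- m("PRO_DS since") - m("PRO_DS before")
  d_non <- m("NON_PRO_DS since") - m("NON_PRO_DS before")
  list(
    double_difference = d_pro - d_non,
    percent_impact = if (is.na(d_non) || abs(d_non) < 1e-9) NA_real_ else d_pro / d_non - 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
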