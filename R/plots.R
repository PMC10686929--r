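#' Plot per-indicator impact estimates
#'
#' Dot plot of percent impact per indicator, coloured by classification and
#' faceted by province. Impacts are shown on an inverse-hyperbolic-sine axis
#' so the handful of very large ratios do not crush the bulk of the
#' distribution.
#'
#' @param object a `dd_estimates` tibble from [estimate_impacts()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot dd_estimates
#' @export
autoplot.dd_estimates <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(!is.na(.data$percent_impact)) |>
    mutate(indicator_id = stats::reorder(.data$indicator_id, .data$percent_impact))
  ggplot2::ggplot(df, ggplot2::aes(x = asinh(.data$percent_impact),
                                   y = .data$indicator_id,
                                   colour = .data$classification)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$province), scales = "free_y") +
    ggplot2::labs(x = "percent impact (asinh scale)", y = NULL,
                  colour = "classification") +
    ggplot2::theme_minimal()
}

#' Plot a domain-level summary
#'
#' Bar chart of the proportion of indicators with a desired effect per
#' domain, split by province.
#'
#' @param object a `dd_summary` from [summarize_impacts()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot dd_summary
#' @export
autoplot.dd_summary <- function(object, ...) {
  ggplot2::ggplot(object$domain,
                  ggplot2::aes(x = .data$pct_positive, y = .data$domain,
                               fill = .data$province)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "% of indicators with desired effect", y = NULL,
                  fill = "province") +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot the monthly series of one indicator by arm
#'
#' Mean monthly value across zones of each arm with the phase boundaries
#' shaded, the visual counterpart of the before/since contrast.
#'
#' @param observations observation tibble.
#' @param indicator an `indicator_id`.
#' @param roster roster tibble.
#' @param calendar a [phase_calendar()].
#' @param province restrict to one province (optional).
#' @return a ggplot object.
#' @export
plot_indicator_series <- function(observations, indicator, roster,
                                  calendar = phase_calendar(), province = NULL) {
  zones <- roster
  if (!is.null(province)) zones <- zones |> filter(.data$province == !!province)
  df <- observations |>
    filter(.data$indicator_id == !!indicator, !.data$is_missing) |>
    inner_join(zones, by = "zone_id") |>
    group_by(.data$month, .data$arm) |>
    summarise(value = mean(.data$value), .groups = "drop")
  shading <- as_tibble(calendar)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(data = shading,
                       ggplot2::aes(xmin = .data$first_month, xmax = .data$last_month,
                                    fill = .data$period),
                       ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_line(ggplot2::aes(x = .data$month, y = .data$value,
                                    colour = .data$arm)) +
    ggplot2::labs(x = NULL, y = indicator, colour = "arm", fill = "period") +
    ggplot2::theme_minimal()
}
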