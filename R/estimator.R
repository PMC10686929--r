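#' Estimator configuration
#'
#' Tuning knobs for the double-difference / percent-impact estimator.
#'
#' @param before_phases phase ids pooled into the "before" mean.
#' @param since_phases phase ids pooled into the "since" mean. Must be
#'   disjoint from `before_phases`; both non-empty.
#' @param denominator_epsilon comparison-arm changes smaller than this in
#'   absolute value are treated as exactly zero: the ratio statistic is
#'   undefined (`NA`) and the estimate is flagged unstable.
#' @param instability_threshold comparison-arm changes below this in absolute
#'   value (default 0.05, half the printed two-decimal resolution of the
#'   reference tables) still yield a value but are flagged unstable.
#' @param rounding_decimals decimals used for display rounding and for the
#'   no-change test (default 2, the reference tables' precision).
#' @param no_change_tolerance after rounding, impacts within this of zero are
#'   classified "No change" (default 0: exact zero after rounding).
#' @param pooling `"pooled"` (default) weights every zone-month value equally
#'   in a phase mean; `"zone_mean"` averages per-zone means instead.
#' @return a list of class `estimator_config`.
#' @export
estimator_config <- function(before_phases = c("T_BEFORE", "T_BASELINE"),
                             since_phases = c("T_PRODS1", "T_PRODS2", "T_PRODS3"),
                             denominator_epsilon = 1e-9,
                             instability_threshold = 0.05,
                             rounding_decimals = 2,
                             no_change_tolerance = 0,
                             pooling = c("pooled", "zone_mean")) {
  pooling <- match.arg(pooling)
  if (length(before_phases) == 0 || length(since_phases) == 0) {
    abort("before_phases and since_phases must be non-empty")
  }
  if (length(intersect(before_phases, since_phases)) > 0) {
    abort("before_phases and since_phases must be disjoint")
  }
  if (denominator_epsilon <= 0 || instability_threshold <= 0) {
    abort("denominator_epsilon and instability_threshold must be positive")
  }
  if (no_change_tolerance < 0) abort("no_change_tolerance must be non-negative")
  structure(list(
    before_phases = before_phases, since_phases = since_phases,
    denominator_epsilon = denominator_epsilon,
    instability_threshold = instability_threshold,
    rounding_decimals = rounding_decimals,
    no_change_tolerance = no_change_tolerance,
    pooling = pooling
  ), class = "estimator_config")
}

#' Phase mean of an indicator for one arm
#'
#' Arithmetic mean of all present zone-month values of `indicator` for zones
#' of the given `arm` (within `province` when given), over the months of the
#' requested phases. Under `pooling = "pooled"` every present zone-month
#' value has equal weight; under `"zone_mean"` each zone's own mean has equal
#' weight (the two agree on balanced panels).
#'
#' @param observations observation tibble.
#' @param indicator an `indicator_id`.
#' @param arm `"PRO_DS"` or `"NON_PRO_DS"`.
#' @param phases character vector of phase ids.
#' @param roster roster tibble.
#' @param calendar a [phase_calendar()].
#' @param province restrict to one province (`NULL` = all zones of the arm).
#' @param pooling `"pooled"` or `"zone_mean"`.
#' @return the mean, or `NA_real_` when no present value exists.
#' @export
phase_mean <- function(observations, indicator, arm, phases,
                       roster, calendar = phase_calendar(),
                       province = NULL, pooling = c("pooled", "zone_mean")) {
  pooling <- match.arg(pooling)
  if (length(phases) == 0) abort("phases must be non-empty")
  months <- phase_months(calendar) |> filter(.data$phase_id %in% phases)
  zones <- roster |> filter(.data$arm == !!arm)
  if (!is.null(province)) zones <- zones |> filter(.data$province == !!province)
  vals <- observations |>
    filter(.data$indicator_id == !!indicator, !.data$is_missing,
           .data$zone_id %in% zones$zone_id, .data$month %in% months$month)
  if (nrow(vals) == 0) return(NA_real_)
  if (pooling == "pooled") {
    mean(vals$value)
  } else {
    vals |>
      group_by(.data$zone_id) |>
      summarise(m = mean(.data$value), .groups = "drop") |>
      pull("m") |>
      mean()
  }
}

#' Double difference and percent impact from four phase means
#'
#' The controlled pre/post contrast: with before/since means for the program
#' arm and the comparison arm,
#' `double_difference = (since_pro - before_pro) - (since_non - before_non)`
#' and the ratio statistic
#' `percent_impact = (since_pro - before_pro) / (since_non - before_non) - 1`,
#' reported as a fraction (0.56 means a 56% larger change in the program arm
#' than in the comparison arm). When the comparison-arm change is zero (within
#' `denominator_epsilon`) the ratio is undefined (`NA`) and the result is
#' flagged unstable; changes below `instability_threshold` keep their value
#' but are also flagged.
#'
#' @param before_pro,since_pro phase means for the program arm.
#' @param before_non,since_non phase means for the comparison arm.
#' @param config an [estimator_config()].
#' @return a one-row tibble: `delta_pro`, `delta_non`, `double_difference`,
#'   `percent_impact`, `unstable_denominator`.
#' @export
#' @examples
#' percent_impact(8.3, 11.1, 7.9, 9.7) # impact rounds to 0.56
percent_impact <- function(before_pro, since_pro, before_non, since_non,
                           config = estimator_config()) {
  means <- c(before_pro, since_pro, before_non, since_non)
  if (length(means) != 4 || anyNA(means) || any(!is.finite(means))) {
    abort("all four phase means must be finite")
  }
  delta_pro <- since_pro - before_pro
  delta_non <- since_non - before_non
  dd <- delta_pro - delta_non
  if (abs(delta_non) < config$denominator_epsilon) {
    p <- NA_real_
    unstable <- TRUE
  } else {
    p <- delta_pro / delta_non - 1
    unstable <- abs(delta_non) < config$instability_threshold
  }
  tibble(delta_pro = delta_pro, delta_non = delta_non,
         double_difference = dd, percent_impact = p,
         unstable_denominator = unstable)
}

#' Fold and literal interpretation of a percent impact
#'
#' Renders the ratio statistic in the reference tables' reporting convention.
#' With `p` the percent impact rounded to `rounding_decimals`:
#' * `p > 0`: fold is `p`, literal `"p times more"`;
#' * `p = 0` (within `no_change_tolerance`): fold 0, literal `"No change"`;
#' * `-1 < p < 0`: fold is `-(1 + p)` (the attenuation ratio of program to
#'   comparison change), literal `"|fold| times less"`;
#' * `p <= -1`: fold is `p`, literal `"|p| times less"`.
#'
#' Note the convention is discontinuous approaching zero from below:
#' `p = -0.02` reads "0.98 times less" while `p = 0` reads "No change".
#'
#' @param percent_impact numeric vector of percent impacts (fractions);
#'   `NA` for undefined.
#' @param config an [estimator_config()].
#' @return a tibble with columns `fold` and `literal`, one row per input.
#' @export
#' @examples
#' interpret_impact(c(-0.70, -1.89, 3.46, 0))
interpret_impact <- function(percent_impact, config = estimator_config()) {
  p <- round_half_up(percent_impact, config$rounding_decimals)
  no_change <- !is.na(p) & abs(p) <= config$no_change_tolerance
  fold <- dplyr::case_when(
    is.na(p) ~ NA_real_,
    no_change ~ 0,
    p > 0 ~ p,
    p > -1 ~ -(1 + p),
    TRUE ~ p
  )
  d <- config$rounding_decimals
  literal <- dplyr::case_when(
    is.na(p) ~ "undefined (unstable denominator)",
    no_change ~ "No change",
    p > 0 ~ paste(format_number(p, d), "times more"),
    TRUE ~ paste(format_number(abs(fold), d), "times less")
  )
  tibble(fold = fold, literal = literal)
}

#' Classify an impact against the indicator's polarity
#'
#' An estimate is a desired ("positive") effect when its sign agrees with the
#' indicator's polarity: an increase for `HIGHER_BETTER` indicators, a
#' decrease for `LOWER_BETTER` ones (so a drop in deaths is POSITIVE). Impacts
#' that round to zero are `NO_CHANGE`; sign/polarity mismatches are
#' `NOT_POSITIVE`; undefined impacts are `UNDEFINED`.
#'
#' @param percent_impact numeric vector (fractions; `NA` for undefined).
#' @param polarity `"HIGHER_BETTER"` or `"LOWER_BETTER"` (recycled).
#' @param config an [estimator_config()].
#' @return character vector in
#'   `c("POSITIVE", "NO_CHANGE", "NOT_POSITIVE", "UNDEFINED")`.
#' @export
#' @examples
#' classify_effect(c(-15.92, 0.45, -0.5, 0), c("LOWER_BETTER", rep("HIGHER_BETTER", 3)))
classify_effect <- function(percent_impact, polarity, config = estimator_config()) {
  bad <- setdiff(unique(polarity[!is.na(polarity)]), polarities())
  if (length(bad) > 0) abort(sprintf("unknown polarity: %s", paste(bad, collapse = ", ")))
  p <- round_half_up(percent_impact, config$rounding_decimals)
  dplyr::case_when(
    is.na(p) ~ "UNDEFINED",
    abs(p) <= config$no_change_tolerance ~ "NO_CHANGE",
    (p > 0 & polarity == "HIGHER_BETTER") | (p < 0 & polarity == "LOWER_BETTER") ~ "POSITIVE",
    TRUE ~ "NOT_POSITIVE"
  )
}

#' Evaluate one indicator in one province
#'
#' Composes the full estimate: the four before/since phase means per arm,
#' the double difference, the percent impact, the fold/literal rendering and
#' the polarity classification. If any phase mean is undefined (no present
#' values) the estimate is returned with classification `UNDEFINED` and the
#' reason in `flag`.
#'
#' @param observations observation tibble.
#' @param indicator an `indicator_id` present in `registry`.
#' @param province province code.
#' @param roster,registry roster and registry tibbles.
#' @param calendar a [phase_calendar()].
#' @param config an [estimator_config()].
#' @return a one-row tibble with the full set of estimate fields.
#' @export
evaluate_indicator <- function(observations, indicator, province,
                               roster, registry,
                               calendar = phase_calendar(),
                               config = estimator_config()) {
  reg_row <- registry |> filter(.data$indicator_id == !!indicator)
  if (nrow(reg_row) == 0) abort(sprintf("indicator '%s' not in registry", indicator))
  pm <- function(arm, phases) {
    phase_mean(observations, indicator, arm, phases, roster, calendar,
               province = province, pooling = config$pooling)
  }
  before_pro <- pm("PRO_DS", config$before_phases)
  since_pro <- pm("PRO_DS", config$since_phases)
  before_non <- pm("NON_PRO_DS", config$before_phases)
  since_non <- pm("NON_PRO_DS", config$since_phases)
  means <- c(before_pro, since_pro, before_non, since_non)

  base <- tibble(
    indicator_id = indicator, province = province,
    domain = reg_row$domain, polarity = reg_row$polarity,
    ind_before_pro = before_pro, ind_since_pro = since_pro,
    ind_before_non = before_non, ind_since_non = since_non
  )
  if (anyNA(means)) {
    return(base |> mutate(
      delta_pro = NA_real_, delta_non = NA_real_, double_difference = NA_real_,
      percent_impact = NA_real_, unstable_denominator = NA,
      fold = NA_real_, literal = "undefined (missing phase mean)",
      classification = "UNDEFINED", flag = "missing phase mean"
    ))
  }
  est <- percent_impact(before_pro, since_pro, before_non, since_non, config)
  interp <- interpret_impact(est$percent_impact, config)
  base |>
    dplyr::bind_cols(est, interp) |>
    mutate(
      classification = classify_effect(.data$percent_impact, .data$polarity, config),
      flag = if_else(.data$unstable_denominator, "unstable denominator", NA_character_)
    )
}

#' Estimate impacts for every retained indicator
#'
#' The pipeline core: applies the missing-year exclusion rule, then evaluates
#' every retained (indicator, province) pair with [evaluate_indicator()].
#'
#' @param observations observation tibble.
#' @param registry,roster registry and roster tibbles.
#' @param calendar a [phase_calendar()].
#' @param config an [estimator_config()].
#' @param exclusion optional precomputed [missing_year_exclusion()] table;
#'   computed from the inputs when `NULL`.
#' @return a tibble of class `dd_estimates`, one row per retained pair, with
#'   the exclusion table attached as attribute `"exclusion"`. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
estimate_impacts <- function(observations, registry, roster,
                             calendar = phase_calendar(),
                             config = estimator_config(),
                             exclusion = NULL) {
  if (nrow(observations) == 0) abort("no observations")
  check_registry(registry)
  if (is.null(exclusion)) {
    exclusion <- missing_year_exclusion(observations, registry, roster, calendar)
  }
  retained <- exclusion |> filter(!.data$excluded)
  out <- purrr::pmap(
    list(retained$indicator_id, retained$province),
    function(ind, prov) {
      evaluate_indicator(observations, ind, prov, roster, registry, calendar, config)
    }
  ) |>
    purrr::list_rbind()
  attr(out, "exclusion") <- exclusion
  class(out) <- c("dd_estimates", class(out))
  out
}

#' @method tidy dd_estimates
#' @export
tidy.dd_estimates <- function(x, ...) {
  as_tibble(x) |>
    select("indicator_id", "province", "domain", "percent_impact",
           "double_difference", "fold", "literal", "classification",
           "unstable_denominator")
}

#' @method glance dd_estimates
#' @export
glance.dd_estimates <- function(x, ...) {
  tibble(
    n_estimates = nrow(x),
    n_positive = sum(x$classification == "POSITIVE"),
    n_no_change = sum(x$classification == "NO_CHANGE"),
    n_not_positive = sum(x$classification == "NOT_POSITIVE"),
    n_undefined = sum(x$classification == "UNDEFINED"),
    n_unstable = sum(x$unstable_denominator %in% TRUE),
    n_excluded = sum(attr(x, "exclusion")$excluded %||% 0L)
  )
}
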