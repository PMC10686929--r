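#' Configuration for the synthetic panel generator
#'
#' Describes a two-province, two-arm monthly panel with known injected
#' program effects. Defaults reproduce the evaluated design's geometry:
#' 3 program + 28 comparison zones in Kongo Central and 7 program + 29
#' comparison zones in Ituri, over the default 75-month calendar.
#'
#' For each indicator the comparison-arm expectation is `mu + tau * t`
#' (`t` = 0-based month index from the start of the span; the linear secular
#' trend is shared by both arms). The program arm follows the same mean
#' during the before phases and adds a constant shift during the since
#' phases, sized so that the expected since-minus-before change in the
#' program arm is `(1 + theta)` times the comparison arm's change; `theta` is
#' therefore the true percent impact in the estimator's own units. Gaussian
#' (`sigma`) or Poisson noise and completely-at-random missingness are
#' applied last.
#'
#' @param provinces tibble with columns `province`, `n_pro`, `n_non` giving
#'   zone counts per arm.
#' @param indicators tibble with one row per simulated indicator: columns
#'   `indicator_id`, `domain`, `polarity`, `mu` (baseline level, >= 0), `tau`
#'   (shared monthly trend), `theta` (target percent impact, fraction),
#'   `noise` (`"gaussian"` or `"poisson"`), `sigma` (gaussian sd),
#'   `missing_rate` (in [0, 1)).
#' @param calendar a [phase_calendar()].
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(provinces = NULL, indicators = NULL,
                             calendar = phase_calendar()) {
  if (is.null(provinces)) {
    provinces <- tibble(
      province = c("KONGO_CENTRAL", "ITURI"),
      n_pro = c(3L, 7L),
      n_non = c(28L, 29L)
    )
  }
  provinces <- as_tibble(provinces)
  assert_columns(provinces, c("province", "n_pro", "n_non"), "provinces spec")
  if (any(provinces$n_pro < 1) || any(provinces$n_non < 1)) {
    abort("each province needs at least one zone per arm")
  }
  if (is.null(indicators)) {
    indicators <- tibble(
      indicator_id = c("sim_coverage", "sim_mortality", "sim_null"),
      domain = c("VACCINATION", "NEWBORN_CHILD", "SERVICE_USE"),
      polarity = c("HIGHER_BETTER", "LOWER_BETTER", "HIGHER_BETTER"),
      mu = 8, tau = 0.05,
      theta = c(0.56, -0.7, 0),
      noise = "gaussian", sigma = 0.1, missing_rate = 0.05
    )
  }
  indicators <- as_tibble(indicators)
  assert_columns(indicators,
                 c("indicator_id", "domain", "polarity", "mu", "tau", "theta",
                   "noise", "sigma", "missing_rate"),
                 "indicators spec")
  if (anyDuplicated(indicators$indicator_id)) abort("duplicate indicator_id")
  if (any(indicators$mu < 0)) abort("baseline level mu must be non-negative")
  if (any(indicators$missing_rate < 0 | indicators$missing_rate >= 1)) {
    abort("missing_rate must be in [0, 1)")
  }
  bad <- setdiff(unique(indicators$noise), c("gaussian", "poisson"))
  if (length(bad) > 0) abort(sprintf("unknown noise model: %s", paste(bad, collapse = ", ")))
  structure(list(provinces = provinces, indicators = indicators,
                 calendar = calendar),
            class = "synthetic_config")
}

# Deterministic 31-bit stream seed per (zone, indicator), independent of the
# number of zones in the roster so adding zones never perturbs existing series.
stream_seed <- function(master_seed, zone_id, indicator_id) {
  key <- paste0(zone_id, "\r", indicator_id)
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 2147483629
  as.integer((h + master_seed) %% 2147483629) + 1L
}

#' Generate a synthetic monthly indicator panel
#'
#' Draws the panel described by a [synthetic_config()]. Output is
#' deterministic given `seed`: each (zone, indicator) series has its own
#' pseudo-random stream derived from the master seed, so regenerating with
#' more zones or indicators leaves existing series byte-identical.
#'
#' @param config a [synthetic_config()].
#' @param seed integer master seed.
#' @return a list with `observations` (long tibble as [read_observations()]
#'   returns), `roster`, `registry` (both in the packaged file schemas) and
#'   `truth` (tibble `indicator_id`, `polarity`, `theta`: the injected
#'   percent impact per indicator).
#' @export
#' @examples
#' panel <- simulate_panel(synthetic_config(), seed = 1)
#' dplyr::count(panel$roster, province, arm)
simulate_panel <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  seed <- as.integer(seed)
  months <- phase_months(config$calendar)
  origin <- calendar_span(config$calendar)[1]
  t_idx <- month_index(months$month, origin)
  since <- months$period == "since"
  # shift sized so E[delta_pro] = (1 + theta) * E[delta_non]
  tbar_before <- mean(t_idx[!since])
  tbar_since <- mean(t_idx[since])

  roster <- purrr::pmap(config$provinces, function(province, n_pro, n_non) {
    tag <- tolower(substr(province, 1, 2))
    tibble(
      zone_id = c(sprintf("%s_pro_%02d", tag, seq_len(n_pro)),
                  sprintf("%s_non_%02d", tag, seq_len(n_non))),
      province = province,
      arm = rep(c("PRO_DS", "NON_PRO_DS"), c(n_pro, n_non))
    )
  }) |>
    purrr::list_rbind()

  registry <- config$indicators |>
    mutate(label = .data$indicator_id,
           provinces = list(config$provinces$province),
           value_kind = "rate") |>
    select("indicator_id", "label", "domain", "polarity", "provinces", "value_kind")

  series <- tidyr::crossing(
    roster |> select("zone_id", "arm"),
    config$indicators |> select("indicator_id", "mu", "tau", "theta",
                                "noise", "sigma", "missing_rate")
  )
  obs <- purrr::pmap(series, function(zone_id, arm, indicator_id, mu, tau, theta,
                                      noise, sigma, missing_rate) {
    mean_t <- mu + tau * t_idx
    if (arm == "PRO_DS") {
      shift <- theta * tau * (tbar_since - tbar_before)
      mean_t <- mean_t + shift * since
    }
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(stream_seed(seed, zone_id, indicator_id))
    value <- if (noise == "poisson") {
      if (any(mean_t < 0)) abort("poisson noise requires non-negative means")
      as.numeric(rpois(length(mean_t), lambda = mean_t))
    } else if (sigma > 0) {
      pmax(0, mean_t + rnorm(length(mean_t), sd = sigma))
    } else {
      mean_t
    }
    miss <- runif(length(mean_t)) < missing_rate
    tibble(zone_id = zone_id, indicator_id = indicator_id, month = months$month,
           value = if_else(miss, NA_real_, value), is_missing = miss)
  }) |>
    purrr::list_rbind()

  list(
    observations = obs,
    roster = roster,
    registry = registry,
    truth = config$indicators |> select("indicator_id", "polarity", "theta")
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Parameter-recovery experiment for the impact estimator
#'
#' Simulates `n_replicates` independent panels from `config`, runs the full
#' estimator on each, and summarises, per indicator, how well the injected
#' percent impact `theta` is recovered: mean and spread of the estimates,
#' undefined-denominator counts (reported, never dropped), and how often the
#' sign classification matches the classification implied by the true
#' `theta` and the indicator's polarity.
#'
#' @param config a [synthetic_config()].
#' @param n_replicates number of replicates (>= 2).
#' @param seed master seed; replicate `r` uses `seed + r`.
#' @param estimator_config an [estimator_config()].
#' @return a tibble with one row per indicator: `theta_true`,
#'   `mean_theta_hat`, `sd_theta_hat`, `bias`, `se_mean` (empirical standard
#'   error of the mean), `n_defined`, `n_undefined`,
#'   `classification_accuracy`.
#' @export
recovery_experiment <- function(config = synthetic_config(), n_replicates = 50,
                                seed = 1, estimator_config = ddimpact::estimator_config()) {
  if (n_replicates < 2) abort("n_replicates must be >= 2")
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    panel <- simulate_panel(config, seed = seed + r)
    purrr::pmap(
      list(panel$truth$indicator_id, panel$truth$polarity, panel$truth$theta),
      function(ind, pol, theta) {
        # province-pooled run: evaluate across all zones at once
        est <- evaluate_all_zones(panel$observations, ind, panel$roster,
                                  panel$registry, config$calendar, estimator_config)
        tibble(replicate = r, indicator_id = ind, theta_true = theta,
               theta_hat = est$percent_impact,
               classification = est$classification, polarity = pol)
      }
    ) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  reps |>
    group_by(.data$indicator_id, .data$theta_true, .data$polarity) |>
    summarise(
      mean_theta_hat = mean(.data$theta_hat, na.rm = TRUE),
      sd_theta_hat = sd(.data$theta_hat, na.rm = TRUE),
      n_defined = sum(!is.na(.data$theta_hat)),
      n_undefined = sum(is.na(.data$theta_hat)),
      classification_accuracy = mean(
        .data$classification == expected_class(.data$theta_true, .data$polarity)
      ),
      .groups = "drop"
    ) |>
    mutate(
      bias = .data$mean_theta_hat - .data$theta_true,
      se_mean = .data$sd_theta_hat / sqrt(pmax(.data$n_defined, 1))
    ) |>
    select("indicator_id", "theta_true", "polarity", "mean_theta_hat",
           "sd_theta_hat", "bias", "se_mean", "n_defined", "n_undefined",
           "classification_accuracy")
}

# classification implied by a true effect and polarity
expected_class <- function(theta, polarity) {
  dplyr::case_when(
    theta == 0 ~ "NO_CHANGE",
    (theta > 0 & polarity == "HIGHER_BETTER") | (theta < 0 & polarity == "LOWER_BETTER") ~ "POSITIVE",
    TRUE ~ "NOT_POSITIVE"
  )
}

# evaluate_indicator without the province restriction: pools every zone of
# each arm (used when a simulated effect is shared across provinces)
evaluate_all_zones <- function(observations, indicator, roster, registry,
                               calendar = phase_calendar(),
                               config = estimator_config()) {
  reg_row <- registry |> filter(.data$indicator_id == !!indicator)
  if (nrow(reg_row) == 0) abort(sprintf("indicator '%s' not in registry", indicator))
  pm <- function(arm, phases) {
    phase_mean(observations, indicator, arm, phases, roster, calendar,
               province = NULL, pooling = config$pooling)
  }
  before_pro <- pm("PRO_DS", config$before_phases)
  since_pro <- pm("PRO_DS", config$since_phases)
  before_non <- pm("NON_PRO_DS", config$before_phases)
  since_non <- pm("NON_PRO_DS", config$since_phases)
  if (anyNA(c(before_pro, since_pro, before_non, since_non))) {
    return(tibble(indicator_id = indicator, percent_impact = NA_real_,
                  double_difference = NA_real_, unstable_denominator = NA,
                  classification = "UNDEFINED"))
  }
  est <- percent_impact(before_pro, since_pro, before_non, since_non, config)
  tibble(
    indicator_id = indicator,
    percent_impact = est$percent_impact,
    double_difference = est$double_difference,
    unstable_denominator = est$unstable_denominator,
    classification = classify_effect(est$percent_impact, reg_row$polarity, config)
  )
}
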