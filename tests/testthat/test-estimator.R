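test_that("phase means pool zone-month values; empty phases are undefined", {
  months <- month_seq_test("2016-01-01", 24)
  roster <- mini_roster(2, 1)
  # one zone, two months: mean of {2, 4} is 3
  obs <- panel_from_values(list(pro_1 = c(2, 4)), months)
  m <- phase_mean(obs, "ind1", "PRO_DS", "T_BEFORE", roster)
  expect_equal(m, 3)
  # all missing -> undefined
  obs_na <- panel_from_values(list(pro_1 = c(NA_real_, NA_real_)), months)
  expect_true(is.na(phase_mean(obs_na, "ind1", "PRO_DS", "T_BEFORE", roster)))
  # balanced two-zone panel: pooled and zone-mean agree
  obs2 <- panel_from_values(list(pro_1 = c(1, 1, 1), pro_2 = c(3, 3, 3)), months)
  expect_equal(phase_mean(obs2, "ind1", "PRO_DS", "T_BEFORE", roster), 2)
  expect_equal(phase_mean(obs2, "ind1", "PRO_DS", "T_BEFORE", roster,
                          pooling = "zone_mean"), 2)
  # unbalanced months distinguish the pooling conventions
  obs3 <- panel_from_values(list(pro_1 = c(1, 1, 1, 1), pro_2 = c(5, NA)), months)
  expect_equal(phase_mean(obs3, "ind1", "PRO_DS", "T_BEFORE", roster), 9 / 5)
  expect_equal(phase_mean(obs3, "ind1", "PRO_DS", "T_BEFORE", roster,
                          pooling = "zone_mean"), 3)
})

test_that("percent impact reproduces the published arithmetic", {
  # 56% larger change in the program arm
  r <- percent_impact(8.3, 11.1, 7.9, 9.7)
  expect_equal(round_half_up(r$percent_impact), 0.56)
  expect_equal(r$double_difference, 1)
  expect_false(r$unstable_denominator)
  # identical changes in both arms: exactly no change
  r0 <- percent_impact(7.4, 9.0, 7.8, 9.4)
  expect_equal(r0$percent_impact, 0)
  expect_equal(percent_impact(1, 2, 1, 2)$double_difference, 0)
  expect_equal(percent_impact(1, 2, 1, 2)$percent_impact, 0)
  # zero comparison-arm change: undefined and unstable
  rz <- percent_impact(0.5, 0.6, 0.2, 0.2)
  expect_true(is.na(rz$percent_impact))
  expect_true(rz$unstable_denominator)
  # sub-threshold but nonzero denominator: defined yet flagged
  ru <- percent_impact(1, 2, 1, 1.01)
  expect_false(is.na(ru$percent_impact))
  expect_true(ru$unstable_denominator)
  expect_error(percent_impact(1, 2, 3, Inf), "finite")
  expect_error(percent_impact(1, 2, 3, NA), "finite")
})

test_that("fold/literal rendering follows the published convention", {
  r <- interpret_impact(c(-0.70, -1.89, 3.46, 0, -0.02, 0.45, -1, 21.29))
  expect_equal(r$fold, c(-0.30, -1.89, 3.46, 0, -0.98, 0.45, -1, 21.29))
  expect_equal(r$literal,
               c("0.3 times less", "1.89 times less", "3.46 times more",
                 "No change", "0.98 times less", "0.45 times more",
                 "1 times less", "21.29 times more"))
  expect_equal(interpret_impact(NA_real_)$literal,
               "undefined (unstable denominator)")
  # rounding happens before interpretation: 0.004 is "No change"
  expect_equal(interpret_impact(0.004)$literal, "No change")
  expect_equal(interpret_impact(0.005)$literal, "0.01 times more")
})

test_that("effect classification respects polarity", {
  expect_equal(classify_effect(-15.92, "LOWER_BETTER"), "POSITIVE")
  expect_equal(classify_effect(0.45, "HIGHER_BETTER"), "POSITIVE")
  expect_equal(classify_effect(-0.5, "HIGHER_BETTER"), "NOT_POSITIVE")
  expect_equal(classify_effect(0.5, "LOWER_BETTER"), "NOT_POSITIVE")
  expect_equal(classify_effect(0, "HIGHER_BETTER"), "NO_CHANGE")
  expect_equal(classify_effect(0.002, "LOWER_BETTER"), "NO_CHANGE")
  expect_equal(classify_effect(NA_real_, "HIGHER_BETTER"), "UNDEFINED")
  expect_error(classify_effect(1, "GOOD"), "polarity")
})

test_that("evaluate_indicator composes the full estimate", {
  months <- phase_months(phase_calendar())$month
  roster <- mini_roster()
  reg <- mini_registry()
  before_n <- 24
  mk <- function(before, since) c(rep(before, before_n), rep(since, 75 - before_n))
  obs <- panel_from_values(
    list(pro_1 = mk(2, 6), non_1 = mk(3, 5)), months)
  est <- evaluate_indicator(obs, "ind1", "KONGO_CENTRAL", roster, reg)
  expect_equal(est$ind_before_pro, 2)
  expect_equal(est$ind_since_pro, 6)
  expect_equal(est$delta_pro, 4)
  expect_equal(est$delta_non, 2)
  expect_equal(est$double_difference, 2)
  expect_equal(est$percent_impact, 1)
  expect_equal(est$literal, "1 times more")
  expect_equal(est$classification, "POSITIVE")
  # constant panel: exact no-change
  obs_c <- panel_from_values(list(pro_1 = rep(4, 75), non_1 = rep(4, 75)), months)
  est_c <- evaluate_indicator(obs_c, "ind1", "KONGO_CENTRAL", roster, reg)
  expect_equal(est_c$double_difference, 0)
  expect_true(is.na(est_c$percent_impact)) # comparison arm did not move at all
  expect_equal(est_c$classification, "UNDEFINED")
  # comparison arm moves, program arm matches it: defined, zero, NO_CHANGE
  obs_m <- panel_from_values(list(pro_1 = mk(2, 4), non_1 = mk(3, 5)), months)
  est_m <- evaluate_indicator(obs_m, "ind1", "KONGO_CENTRAL", roster, reg)
  expect_equal(est_m$percent_impact, 0)
  expect_equal(est_m$classification, "NO_CHANGE")
  # a fully missing arm yields an UNDEFINED estimate with a flag
  obs_na <- panel_from_values(list(pro_1 = mk(2, 6),
                                   non_1 = rep(NA_real_, 75)), months)
  est_na <- evaluate_indicator(obs_na, "ind1", "KONGO_CENTRAL", roster, reg)
  expect_equal(est_na$classification, "UNDEFINED")
  expect_equal(est_na$flag, "missing phase mean")
  expect_error(evaluate_indicator(obs, "nope", "KONGO_CENTRAL", roster, reg),
               "not in registry")
})

test_that("estimator agrees with the brute-force oracle on random panels", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    p <- random_panel()
    est <- evaluate_indicator(p$observations, "ind1", "KONGO_CENTRAL",
                              p$roster, p$registry, p$calendar)
    orc <- oracle_percent_impact(p$observations, p$roster, p$calendar)
    expect_equal(est$double_difference, orc$double_difference, tolerance = 1e-12)
    if (is.na(orc$percent_impact)) {
      expect_true(is.na(est$percent_impact))
    } else {
      expect_equal(est$percent_impact, orc$percent_impact, tolerance = 1e-12)
      worst <- max(worst, abs(est$percent_impact - orc$percent_impact))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("percent impact is scale- and translation-invariant", {
  set.seed(202)
  for (i in 1:20) {
    p <- random_panel()
    base <- evaluate_indicator(p$observations, "ind1", "KONGO_CENTRAL",
                               p$roster, p$registry, p$calendar)
    c_mult <- stats::runif(1, 0.5, 10)
    scaled <- dplyr::mutate(p$observations, value = value * c_mult)
    est_s <- evaluate_indicator(scaled, "ind1", "KONGO_CENTRAL",
                                p$roster, p$registry, p$calendar)
    shifted <- dplyr::mutate(p$observations, value = value + 7.3)
    est_t <- evaluate_indicator(shifted, "ind1", "KONGO_CENTRAL",
                                p$roster, p$registry, p$calendar)
    if (!is.na(base$percent_impact)) {
      expect_equal(est_s$percent_impact, base$percent_impact, tolerance = 1e-9)
      expect_equal(est_t$percent_impact, base$percent_impact, tolerance = 1e-9)
    }
    expect_equal(est_s$double_difference, base$double_difference * c_mult,
                 tolerance = 1e-9)
    expect_equal(est_t$double_difference, base$double_difference,
                 tolerance = 1e-9)
  }
})

test_that("swapping arms maps the ratio to its reciprocal", {
  set.seed(303)
  for (i in 1:20) {
    p <- random_panel()
    est <- evaluate_indicator(p$observations, "ind1", "KONGO_CENTRAL",
                              p$roster, p$registry, p$calendar)
    swapped_roster <- dplyr::mutate(
      p$roster, arm = ifelse(arm == "PRO_DS", "NON_PRO_DS", "PRO_DS"))
    est_sw <- evaluate_indicator(p$observations, "ind1", "KONGO_CENTRAL",
                                 swapped_roster, p$registry, p$calendar)
    if (!is.na(est$percent_impact) && !is.na(est_sw$percent_impact)) {
      expect_equal((1 + est$percent_impact) * (1 + est_sw$percent_impact), 1,
                   tolerance = 1e-9)
    }
  }
})

test_that("estimate_impacts runs the exclusion rule then evaluates retained pairs", {
  months <- phase_months(phase_calendar())$month
  roster <- mini_roster()
  reg <- mini_registry(ids = c("ind1", "ind2"),
                       polarity = c("HIGHER_BETTER", "LOWER_BETTER"),
                       provinces = list("KONGO_CENTRAL", "KONGO_CENTRAL"))
  mk <- function(before, since) c(rep(before, 24), rep(since, 51))
  obs <- dplyr::bind_rows(
    panel_from_values(list(pro_1 = mk(2, 6), non_1 = mk(3, 5)), months, "ind1"),
    # ind2 observed only in 2021-2022 -> five fully missing years -> excluded
    panel_from_values(list(pro_1 = c(rep(NA, 60), rep(1, 15)),
                           non_1 = c(rep(NA, 60), rep(2, 15))), months, "ind2")
  )
  est <- estimate_impacts(obs, reg, roster)
  expect_s3_class(est, "dd_estimates")
  expect_equal(est$indicator_id, "ind1")
  excl <- attr(est, "exclusion")
  expect_true(excl$excluded[excl$indicator_id == "ind2"])
  g <- glance(est)
  expect_equal(g$n_estimates, 1)
  expect_equal(g$n_positive, 1)
  expect_equal(g$n_excluded, 1)
  td <- tidy(est)
  expect_true(all(c("percent_impact", "literal", "classification") %in% names(td)))
  expect_error(estimate_impacts(obs[0, ], reg, roster), "no observations")
})
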