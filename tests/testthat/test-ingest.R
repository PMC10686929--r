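write_obs_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c("zone_id,indicator_id,year,month,value", lines), path)
  path
}

test_that("valid rows pass through and blanks become missing", {
  path <- write_obs_file(c(
    "pro_1,ind1,2016,1,4.5",
    "pro_1,ind1,2016,2,",
    "non_1,ind1,2017,12,0",
    "non_1,ind1,2022,3,9.25"
  ))
  obs <- read_observations(path, mini_registry(), mini_roster())
  expect_equal(nrow(obs), 4)
  expect_equal(ingest_report(obs)$n_rows_rejected, 0)
  expect_equal(obs$is_missing, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(obs$value[2], NA_real_)
  expect_equal(obs$month[1], as.Date("2016-01-01"))
})

test_that("referential and schema violations reject rows with reasons", {
  path <- write_obs_file(c(
    "ZZZ,ind1,2016,1,1",       # unknown zone
    "pro_1,nope,2016,1,1",     # unknown indicator
    "pro_1,ind1,2016,13,1",    # malformed month
    "pro_1,ind1,2015,1,1",     # outside span
    "pro_1,ind1,2016,1,-3",    # negative value
    "pro_1,ind1,2016,1,abc",   # non-numeric
    "pro_1,ind1,2016,3,2"      # valid
  ))
  expect_warning(
    obs <- read_observations(path, mini_registry(), mini_roster()),
    "rejected"
  )
  rep <- ingest_report(obs)
  expect_equal(nrow(obs), 1)
  expect_equal(rep$n_rows_read, 7)
  expect_equal(rep$n_rows_rejected, 6)
  expect_setequal(rep$rejected$reason,
                  c("unknown zone", "unknown indicator", "malformed month",
                    "month outside study span", "negative value",
                    "non-numeric value"))
  expect_error(read_observations(tempfile(), mini_registry(), mini_roster()),
               "not found")
})

test_that("ingest and write-back round-trip valid files", {
  path <- write_obs_file(c(
    "pro_1,ind1,2016,1,4.5",
    "pro_1,ind1,2016,2,",
    "non_1,ind1,2018,7,12"
  ))
  obs <- read_observations(path, mini_registry(), mini_roster())
  out <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, out)
  obs2 <- read_observations(out, mini_registry(), mini_roster())
  expect_equal(as.data.frame(obs), as.data.frame(obs2))
})

test_that("missing-year exclusion excludes on more than two fully missing years", {
  cal <- phase_calendar()
  roster <- mini_roster()
  reg <- mini_registry()
  all_months <- phase_months(cal)$month
  full <- tidyr::crossing(zone_id = roster$zone_id, month = all_months) |>
    dplyr::mutate(indicator_id = "ind1", value = 1, is_missing = FALSE)
  blank_years <- function(obs, years) {
    dplyr::mutate(obs,
      is_missing = is_missing | format(month, "%Y") %in% years,
      value = ifelse(is_missing, NA_real_, value))
  }
  # no missingness: retained
  ex0 <- missing_year_exclusion(full, reg, roster, cal)
  expect_false(ex0$excluded)
  expect_equal(ex0$n_missing_years, 0)
  # exactly two fully missing years: boundary, still retained
  ex2 <- missing_year_exclusion(blank_years(full, c("2016", "2017")), reg, roster, cal)
  expect_false(ex2$excluded)
  expect_equal(ex2$n_missing_years, 2)
  # three fully missing years: excluded
  ex3 <- missing_year_exclusion(blank_years(full, c("2016", "2017", "2018")),
                                reg, roster, cal)
  expect_true(ex3$excluded)
  expect_equal(ex3$n_missing_years, 3)
  expect_match(ex3$reason, "calendar years")
  # a single present month anywhere in a year rescues that year
  rescue <- blank_years(full, c("2016", "2017", "2018"))
  rescue$is_missing[rescue$month == as.Date("2018-06-01") &
                      rescue$zone_id == "non_1"] <- FALSE
  rescue$value[rescue$month == as.Date("2018-06-01") &
                 rescue$zone_id == "non_1"] <- 5
  expect_false(missing_year_exclusion(rescue, reg, roster, cal)$excluded)
})

test_that("exclusion is monotone: adding observations never excludes", {
  cal <- phase_calendar()
  roster <- mini_roster()
  reg <- mini_registry()
  all_months <- phase_months(cal)$month
  set.seed(42)
  for (i in 1:5) {
    base <- tidyr::crossing(zone_id = roster$zone_id, month = all_months) |>
      dplyr::mutate(indicator_id = "ind1",
                    is_missing = stats::runif(dplyr::n()) < 0.7,
                    value = ifelse(is_missing, NA_real_, 1))
    before <- missing_year_exclusion(base, reg, roster, cal)
    # reveal some previously missing values
    richer <- base
    flip <- which(richer$is_missing)[seq_len(min(30, sum(richer$is_missing)))]
    richer$is_missing[flip] <- FALSE
    richer$value[flip] <- 2
    after <- missing_year_exclusion(richer, reg, roster, cal)
    expect_false(any(!before$excluded & after$excluded))
  }
})

test_that("month-count exclusion rule is available as the stricter variant", {
  cal <- phase_calendar()
  roster <- mini_roster()
  reg <- mini_registry()
  all_months <- phase_months(cal)$month
  # 25 scattered missing months across years: retained under the year rule,
  # excluded under the month rule
  obs <- tidyr::crossing(zone_id = roster$zone_id, month = all_months) |>
    dplyr::mutate(indicator_id = "ind1", value = 1, is_missing = FALSE)
  gap_months <- all_months[seq(1, 74, by = 3)][1:25]
  obs <- obs |>
    dplyr::mutate(is_missing = month %in% gap_months & zone_id == "pro_1")
  # pro_1 missing only: months still covered by non_1, so nothing is missing
  ex <- missing_year_exclusion(obs, reg, roster, cal, rule = "months")
  expect_false(ex$excluded)
  obs_both <- obs |> dplyr::mutate(is_missing = month %in% gap_months,
                                   value = ifelse(is_missing, NA_real_, value))
  expect_false(missing_year_exclusion(obs_both, reg, roster, cal)$excluded)
  expect_true(missing_year_exclusion(obs_both, reg, roster, cal,
                                     rule = "months")$excluded)
})
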