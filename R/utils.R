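# Shared helpers: month arithmetic and display rounding.

#' Round half away from zero
#'
#' Display rounding used throughout the package: ties are rounded away from
#' zero (so 0.005 -> 0.01 and -0.005 -> -0.01), unlike [round()], which rounds
#' ties to even. All published comparison values are printed at two decimals
#' under this convention; internal computations always keep full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.565, -0.565, 2.5e-3), 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by a relative epsilon so that values intended to be exact ties
  # (e.g. 0.565 stored as 0.56499999...) round as printed
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# First day of the month containing `x`
month_floor <- function(x) {
  as.Date(format(as.Date(x), "%Y-%m-01"))
}

# Build the first-of-month Date for a (year, month) pair
make_month <- function(year, month) {
  as.Date(sprintf("%04d-%02d-01", as.integer(year), as.integer(month)))
}

# Sequence of months (first-of-month Dates), inclusive
month_seq <- function(from, to) {
  seq(month_floor(from), month_floor(to), by = "month")
}

# Number of whole months from `from` to `to`, inclusive
n_months <- function(from, to) {
  length(month_seq(from, to))
}

# 0-based month index relative to an origin month
month_index <- function(month, origin) {
  m <- as.POSIXlt(month_floor(month))
  o <- as.POSIXlt(month_floor(origin))
  (m$year - o$year) * 12L + (m$mon - o$mon)
}

format_number <- function(x, digits = 2) {
  # fixed rounding then trailing-zero trim: 0.30 -> "0.3", 3.46 -> "3.46"
  s <- formatC(round_half_up(x, digits), format = "f", digits = digits)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
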