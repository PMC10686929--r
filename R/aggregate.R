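#' Summarise classified estimates into domain-level proportions
#'
#' Aggregates per-indicator estimates into the published evaluation's
#' accounting: per domain and province, the number of indicators, the number
#' with a desired ("positive") effect, and the complementary "without effect"
#' count that pools `NO_CHANGE`, `NOT_POSITIVE` and `UNDEFINED` so the two
#' counts always sum to the total. Percentages are reported to one decimal;
#' the cross-province mean is the unweighted average of the two province
#' percentages (not the pooled proportion).
#'
#' @param estimates a [estimate_impacts()] result (or any data frame with
#'   `indicator_id`, `province`, `classification`).
#' @param registry registry tibble; every estimated indicator must appear in
#'   it (hard error otherwise). Supplies the domain grouping; when `NULL` the
#'   estimates' own `domain` column is used.
#' @return an object of class `dd_summary` (see [summarize_counts()]).
#' @export
summarize_impacts <- function(estimates, registry = NULL) {
  assert_columns(estimates, c("indicator_id", "province", "classification"),
                 "estimates")
  if (!is.null(registry)) {
    unknown <- setdiff(estimates$indicator_id, registry$indicator_id)
    if (length(unknown) > 0) {
      abort(sprintf("estimate(s) for indicator(s) absent from registry: %s",
                    paste(unknown, collapse = ", ")))
    }
    estimates <- estimates |>
      select(-dplyr::any_of("domain")) |>
      left_join(registry |> select("indicator_id", "domain"), by = "indicator_id")
  }
  assert_columns(estimates, "domain", "estimates (after registry join)")
  counts <- estimates |>
    group_by(.data$domain, .data$province) |>
    summarise(
      n_indicators = n(),
      n_positive = sum(.data$classification == "POSITIVE"),
      n_no_change = sum(.data$classification == "NO_CHANGE"),
      n_not_positive = sum(.data$classification == "NOT_POSITIVE"),
      n_undefined = sum(.data$classification == "UNDEFINED"),
      .groups = "drop"
    )
  summarize_counts(counts)
}

#' Summarise domain-level positive-effect counts
#'
#' Lower-level entry point taking precomputed counts (as published summary
#' tables provide them) rather than per-indicator estimates.
#'
#' @param counts a data frame with columns `domain`, `province`,
#'   `n_indicators`, `n_positive` (optionally the finer `n_no_change`,
#'   `n_not_positive`, `n_undefined` breakdown).
#' @return an object of class `dd_summary`: a list with
#' * `domain`: per domain x province counts with `n_no_effect`
#'   (`= n_indicators - n_positive`), `pct_positive`, `pct_no_effect`
#'   (percentages, 1 decimal);
#' * `domain_means`: per domain, the unweighted cross-province mean of
#'   `pct_positive` and `pct_no_effect`;
#' * `province`: per-province totals with the same percentage columns;
#' * `overall`: one row with total counts and the cross-province mean
#'   percentages.
#' @export
summarize_counts <- function(counts) {
  counts <- as_tibble(counts)
  assert_columns(counts, c("domain", "province", "n_indicators", "n_positive"),
                 "counts")
  if (any(counts$n_positive > counts$n_indicators)) {
    abort("n_positive cannot exceed n_indicators")
  }
  pct <- function(num, den) if_else(den > 0, round_half_up(100 * num / den, 1), NA_real_)
  domain <- counts |>
    mutate(
      n_no_effect = .data$n_indicators - .data$n_positive,
      pct_positive = pct(.data$n_positive, .data$n_indicators),
      pct_no_effect = pct(.data$n_no_effect, .data$n_indicators)
    )
  domain_means <- domain |>
    group_by(.data$domain) |>
    summarise(
      n_indicators = sum(.data$n_indicators),
      n_positive = sum(.data$n_positive),
      n_no_effect = sum(.data$n_no_effect),
      mean_pct_positive = round_half_up(mean(.data$pct_positive), 1),
      mean_pct_no_effect = round_half_up(mean(.data$pct_no_effect), 1),
      .groups = "drop"
    )
  province <- domain |>
    group_by(.data$province) |>
    summarise(
      n_indicators = sum(.data$n_indicators),
      n_positive = sum(.data$n_positive),
      n_no_effect = sum(.data$n_no_effect),
      .groups = "drop"
    ) |>
    mutate(
      pct_positive = pct(.data$n_positive, .data$n_indicators),
      pct_no_effect = pct(.data$n_no_effect, .data$n_indicators)
    )
  overall <- tibble(
    n_indicators = sum(province$n_indicators),
    n_positive = sum(province$n_positive),
    n_no_effect = sum(province$n_no_effect),
    mean_pct_positive = round_half_up(mean(province$pct_positive), 1),
    mean_pct_no_effect = round_half_up(mean(province$pct_no_effect), 1)
  )
  structure(list(domain = domain, domain_means = domain_means,
                 province = province, overall = overall),
            class = "dd_summary")
}

#' @export
print.dd_summary <- function(x, ...) {
  cat("Domain-level positive-effect summary\n")
  print(x$domain, n = Inf)
  cat("Province totals:\n")
  print(x$province)
  cat(sprintf("Overall: %d/%d positive; cross-province mean %.1f%% positive\n",
              x$overall$n_positive, x$overall$n_indicators,
              x$overall$mean_pct_positive))
  invisible(x)
}

#' @method tidy dd_summary
#' @export
tidy.dd_summary <- function(x, ...) x$domain

#' @method glance dd_summary
#' @export
glance.dd_summary <- function(x, ...) x$overall

#' Render estimate and summary tables to files
#'
#' Writes per-indicator impact tables (the four phase means, double
#' difference, percent impact, fold and literal text) and the domain-level
#' summary, either as CSV (`estimates.csv`, `domain_summary.csv`,
#' `province_summary.csv`) or as one markdown document per province plus a
#' summary (`report_<province>.md`, `summary.md`).
#'
#' @param estimates a [estimate_impacts()] result (or compatible tibble).
#' @param summary a `dd_summary`; computed from `estimates` when `NULL`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"md"`.
#' @return character vector of files written, invisibly.
#' @export
render_tables <- function(estimates, summary = NULL, dir, format = c("csv", "md")) {
  if (!format[1] %in% c("csv", "md")) {
    abort(sprintf("unknown report format '%s'", format[1]))
  }
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(summary) && nrow(estimates) > 0) {
    summary <- summarize_impacts(estimates)
  }
  written <- character()
  if (format == "csv") {
    f <- file.path(dir, "estimates.csv")
    readr::write_csv(as_tibble(estimates), f)
    written <- c(written, f)
    if (!is.null(summary)) {
      f2 <- file.path(dir, "domain_summary.csv")
      readr::write_csv(summary$domain, f2)
      f3 <- file.path(dir, "province_summary.csv")
      readr::write_csv(summary$province, f3)
      written <- c(written, f2, f3)
    }
  } else {
    provs <- unique(estimates$province)
    for (prov in provs) {
      f <- file.path(dir, paste0("report_", tolower(prov), ".md"))
      tab <- estimates |>
        filter(.data$province == prov) |>
        mutate(across(dplyr::where(is.numeric), ~ round_half_up(.x, 2))) |>
        select(dplyr::any_of(c("domain", "indicator_id", "ind_before_pro",
                               "ind_since_pro", "ind_before_non", "ind_since_non",
                               "percent_impact", "fold", "literal", "classification")))
      writeLines(c(paste("#", prov, "per-indicator impacts"), "", md_table(tab)), f)
      written <- c(written, f)
    }
    if (!is.null(summary)) {
      f <- file.path(dir, "summary.md")
      writeLines(c("# Domain-level summary", "", md_table(summary$domain), "",
                   "## Province totals", "", md_table(summary$province)), f)
      written <- c(written, f)
    }
    if (length(provs) == 0) {
      f <- file.path(dir, "report_empty.md")
      writeLines("# Per-indicator impacts\n\n(no estimates)", f)
      written <- c(written, f)
    }
  }
  invisible(written)
}

md_table <- function(df) {
  if (nrow(df) == 0) return("(empty)")
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  cells <- matrix(as.character(cells), nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
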