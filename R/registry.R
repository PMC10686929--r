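#' Impact domains, polarities, arms and provinces
#'
#' Fixed vocabularies used across the package. Indicators belong to one of six
#' impact domains; their polarity states which direction of change is desired
#' (`HIGHER_BETTER` for e.g. vaccination coverage, `LOWER_BETTER` for e.g.
#' deaths or attrition). Health zones belong to the program (`PRO_DS`) or
#' comparison (`NON_PRO_DS`) arm.
#'
#' @name vocabularies
#' @export
impact_domains <- function() {
  c("SUPERVISION_MANAGEMENT", "SERVICE_USE", "NUTRITIONAL_HEALTH",
    "VACCINATION", "REPRODUCTIVE_MATERNAL", "NEWBORN_CHILD")
}

#' @rdname vocabularies
#' @export
polarities <- function() c("HIGHER_BETTER", "LOWER_BETTER")

#' @rdname vocabularies
#' @export
arms <- function() c("PRO_DS", "NON_PRO_DS")

#' Read an indicator registry
#'
#' The registry is the single source of truth for what each indicator is:
#' its impact domain, its polarity, which provinces report it, and the kind
#' of value it carries. One CSV row per indicator with columns
#' `indicator_id,label,domain,polarity,provinces,value_kind`; `provinces` is a
#' `;`-separated list. The packaged registry
#' (`system.file("extdata/indicator_registry.csv", package = "ddimpact")`)
#' reproduces the published evaluation's 74 Kongo Central / 65 Ituri
#' indicators.
#'
#' @param path path to a registry CSV.
#' @return a tibble with one row per indicator; `provinces` is a list-column
#'   of character vectors.
#' @export
read_indicator_registry <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  assert_columns(raw, c("indicator_id", "label", "domain", "polarity",
                        "provinces", "value_kind"), "indicator registry")
  reg <- raw |>
    mutate(provinces = strsplit(.data$provinces, ";", fixed = TRUE))
  check_registry(reg)
  reg
}

check_registry <- function(registry) {
  dup <- registry$indicator_id[duplicated(registry$indicator_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate indicator_id in registry: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  bad_domain <- setdiff(unique(registry$domain), impact_domains())
  if (length(bad_domain) > 0) {
    abort(sprintf("unknown domain(s): %s", paste(bad_domain, collapse = ", ")))
  }
  bad_pol <- setdiff(unique(registry$polarity), polarities())
  if (length(bad_pol) > 0) {
    abort(sprintf("unknown polarity value(s): %s", paste(bad_pol, collapse = ", ")))
  }
  if (any(lengths(registry$provinces) == 0)) {
    abort("every indicator must list at least one province")
  }
  invisible(registry)
}

# one row per (indicator, province)
registry_pairs <- function(registry) {
  registry |>
    select("indicator_id", "label", "domain", "polarity", "value_kind", "provinces") |>
    tidyr::unnest_longer("provinces", values_to = "province")
}

#' Validate an indicator registry
#'
#' Checks structural invariants (non-empty, unique ids, known domains and
#' polarities, non-empty province lists) and tallies indicators per province
#' and per domain so totals can be checked against an expected design (the
#' packaged registry totals 74 for Kongo Central and 65 for Ituri).
#'
#' @param registry a registry tibble from [read_indicator_registry()].
#' @return an object of class `registry_validation`: a list with
#'   `province_counts` (tibble `province`, `n`), `domain_counts` (tibble
#'   `domain`, `province`, `n`) and `n_indicators`.
#' @export
validate_registry <- function(registry) {
  if (!is.data.frame(registry) || nrow(registry) == 0) {
    abort("registry must be a non-empty data frame")
  }
  check_registry(registry)
  pairs <- registry_pairs(registry)
  out <- list(
    n_indicators = nrow(registry),
    province_counts = count(pairs, .data$province, name = "n"),
    domain_counts = count(pairs, .data$domain, .data$province, name = "n")
  )
  structure(out, class = "registry_validation")
}

#' @export
print.registry_validation <- function(x, ...) {
  cat("Indicator registry:", x$n_indicators, "distinct indicators\n")
  cat("Per province:\n")
  print(x$province_counts)
  cat("Per domain and province:\n")
  print(x$domain_counts, n = Inf)
  invisible(x)
}

#' Read a health-zone roster
#'
#' CSV with header `zone_id,province,arm`; each zone belongs to exactly one
#' province and one arm (`PRO_DS` or `NON_PRO_DS`). A synthetic roster
#' matching the published design (3 + 28 Kongo Central zones, 7 + 29 Ituri
#' zones) ships as `extdata/synthetic_zone_roster.csv`; the comparison-zone
#' names in it are placeholders.
#'
#' @param path path to a roster CSV.
#' @return a tibble with columns `zone_id`, `province`, `arm`.
#' @export
read_zone_roster <- function(path) {
  roster <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
  assert_columns(roster, c("zone_id", "province", "arm"), "zone roster")
  if (anyDuplicated(roster$zone_id)) abort("duplicate zone_id in roster")
  bad <- setdiff(unique(roster$arm), arms())
  if (length(bad) > 0) abort(sprintf("unknown arm(s): %s", paste(bad, collapse = ", ")))
  roster
}

#' Paths to the packaged reference data
#'
#' Convenience accessor for the plain-text reference files installed with the
#' package: the indicator registry, the synthetic zone roster, the published
#' per-indicator impact rows (with their four phase means, printed impact,
#' fold, literal text and a per-row reproducibility flag) and the published
#' domain-level positive-effect counts.
#'
#' @param file one of `"registry"`, `"roster"`, `"impacts"`, `"domain_counts"`.
#' @return the installed file path.
#' @export
ddimpact_example <- function(file = c("registry", "roster", "impacts", "domain_counts")) {
  file <- match.arg(file)
  name <- switch(file,
    registry = "indicator_registry.csv",
    roster = "synthetic_zone_roster.csv",
    impacts = "reference_impacts.csv",
    domain_counts = "reference_domain_counts.csv"
  )
  system.file("extdata", name, package = "ddimpact", mustWork = TRUE)
}
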