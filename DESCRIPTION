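Package: ddimpact
Title: Controlled Difference-in-Differences Impact Assessment for Health
    Indicator Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for controlled longitudinal (pre/post with comparison arm)
    impact assessment of routine health-system indicators, as used to evaluate
    health-zone strengthening programs in the Democratic Republic of Congo.
    Implements the double-difference and ratio percent-impact statistic over a
    five-phase study calendar, the fold/literal interpretation convention,
    polarity-based positive-effect classification, the missing-year exclusion
    rule, and domain-level aggregation of positive-effect proportions. Includes
    a synthetic monthly panel generator with injected program effects and a
    parameter-recovery harness, plus packaged reference tables from a published
    two-province program evaluation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
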