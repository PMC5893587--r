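Package: creeltrends
Title: Trend Analysis of Multispecies Creel-Survey Landings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term fisheries-dependent (creel survey)
    records from multispecies coral-reef fisheries. Provides record filtering
    with exact biomass accounting, length-to-weight allometric conversion with
    provenance-tiered coefficients, optimal natural-breaks (Fisher dynamic
    programming) body-size classification, large-to-small biomass ratios,
    moving-average smoothing, weighted candidate regressions (linear,
    exponential, power, quadratic) selected by AIC subject to residual
    diagnostics, and a four-criterion classifier that assigns each target
    species a potential management category (size-based versus
    gear/quota/area policies). A synthetic creel-data generator with known
    per-species trend structure supports end-to-end validation.
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
    lmtest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
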