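#' Analysis configuration
#'
#' Collects every numeric constant and switch the pipeline uses, with the
#' study defaults. All thresholds must be positive.
#'
#' @param family_pct Families contributing less than this percent of overall
#'   landed biomass are removed (strict `<`; exactly this share is kept).
#' @param species_pct Species contributing less than this percent of their
#'   family's landed biomass are removed (strict `<`).
#' @param dominance_pct A family is "dominant" in a fishery when it exceeds
#'   this percent of the fishery's landed biomass.
#' @param coverage_pct Species-level trend series are built for the top
#'   species that cumulatively reach this percent of fishery biomass.
#' @param min_n Minimum total measured fish for a species-level series.
#' @param timeframe_kg Minimum rolling-average annual landings (kg/yr) that
#'   defines each fishery's analysis timeframe.
#' @param window Moving-average window (odd number of years).
#' @param alpha Significance level for model selection and residual checks.
#' @param gvf_increment Minimum gain in goodness-of-variance-fit required to
#'   prefer 3 body-size classes over 2.
#' @param length_tolerance Records with fork length above
#'   `max_length_mm * length_tolerance` are treated as measurement errors.
#' @param out_of_region_sectors Sector labels dropped by the location filter.
#' @param strict Error (rather than drop) when a species has no attributes.
#' @param family_filter_per_fishery Compute the family 1% filter within each
#'   fishery instead of pooled across fisheries.
#' @param effect_metric How the classifier measures effect size:
#'   `"std_slope"` (standardised linear slope with its SE) or
#'   `"net_change_frac"` (fractional net change, SE propagated from the
#'   leading coefficient).
#' @param expansion_year Optional year annotated on plots (e.g. a marina
#'   construction opening new grounds).
#' @param seed RNG seed for any simulation the pipeline performs.
#' @return An object of class `creel_config` (a named list).
#' @export
creel_config <- function(family_pct = 1, species_pct = 1, dominance_pct = 10,
                         coverage_pct = 70, min_n = 50, timeframe_kg = 50,
                         window = 3, alpha = 0.05, gvf_increment = 0.10,
                         length_tolerance = 1.5,
                         out_of_region_sectors = character(),
                         strict = TRUE, family_filter_per_fishery = FALSE,
                         effect_metric = c("std_slope", "net_change_frac"),
                         expansion_year = NULL, seed = NULL) {
  effect_metric <- match.arg(effect_metric)
  cfg <- list(
    family_pct = family_pct, species_pct = species_pct,
    dominance_pct = dominance_pct, coverage_pct = coverage_pct,
    min_n = min_n, timeframe_kg = timeframe_kg,
    window = check_window(window), alpha = alpha,
    gvf_increment = gvf_increment, length_tolerance = length_tolerance,
    out_of_region_sectors = out_of_region_sectors, strict = strict,
    family_filter_per_fishery = family_filter_per_fishery,
    effect_metric = effect_metric, expansion_year = expansion_year,
    seed = seed
  )
  num <- c("family_pct", "species_pct", "dominance_pct", "coverage_pct",
           "min_n", "timeframe_kg", "alpha", "gvf_increment",
           "length_tolerance")
  bad <- num[vapply(cfg[num], function(v) !is.numeric(v) || v <= 0, logical(1))]
  if (length(bad)) {
    abort(paste0("Config thresholds must be positive: ", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "creel_config")
}

#' Read and write a configuration file
#'
#' Configurations round-trip through YAML unchanged.
#'
#' @param config A [creel_config()].
#' @param path File path.
#' @return `read_config()` returns a `creel_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "creel_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$out_of_region_sectors <- as.character(unlist(raw$out_of_region_sectors) %||% character())
  do.call(creel_config, raw)
}
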