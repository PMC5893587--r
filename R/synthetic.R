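#' Specify a deterministic trend path
#'
#' A trend path describes how a quantity (a species' proportional
#' contribution to landings, or its mean fork length) moves over the study
#' years. Four shapes cover the fishery scenarios the trend models are built
#' to detect: `constant`, `linear` (steady drift), `exponential` (fast change
#' that saturates), and `humped` (a peak or trough mid-series).
#'
#' All forms are parameterised so that the value at the first year is `start`
#' and the value at the last year is `start + net_change`; the signed net
#' change over the series is therefore `net_change` regardless of form. For
#' the humped form an extra amplitude `hump` sets the height of the mid-series
#' excursion (added as `hump * 4u(1-u)` on the unit time scale `u`); it
#' defaults to `-net_change`, i.e. a dip/peak of the same magnitude as the
#' drift, or to `start / 2` when `net_change` is zero.
#'
#' @param form One of `"constant"`, `"linear"`, `"exponential"`, `"humped"`.
#' @param start Value at the first year (proportion, or mm).
#' @param net_change Signed change from first to last year.
#' @param hump Mid-series excursion for the humped form (same units as
#'   `start`); ignored otherwise.
#' @param rate Saturation rate of the exponential form (dimensionless; larger
#'   means the change is concentrated earlier in the series).
#' @return An object of class `trend_spec`.
#' @export
#' @examples
#' evaluate_path(trend_spec("linear", 350, -100), n_years = 5)
trend_spec <- function(form = c("constant", "linear", "exponential", "humped"),
                       start, net_change = 0, hump = NULL, rate = 3) {
  form <- match.arg(form)
  stopifnot(is.numeric(start), length(start) == 1L, is.finite(start),
            is.numeric(net_change), length(net_change) == 1L, is.finite(net_change))
  if (form == "constant") net_change <- 0
  if (is.null(hump)) {
    hump <- if (net_change != 0) -net_change else start / 2
  }
  structure(
    list(form = form, start = start, net_change = net_change,
         hump = hump, rate = rate),
    class = "trend_spec"
  )
}

#' Evaluate a trend path over a series of years
#'
#' @param path A [trend_spec()].
#' @param n_years Number of annual timesteps.
#' @return Numeric vector of length `n_years`; the first element equals
#'   `start` and the last equals `start + net_change`.
#' @export
evaluate_path <- function(path, n_years) {
  stopifnot(inherits(path, "trend_spec"), n_years >= 2)
  u <- seq(0, 1, length.out = n_years)
  with(path, switch(form,
    constant    = rep(start, n_years),
    linear      = start + net_change * u,
    exponential = start + net_change * (1 - exp(-rate * u)) / (1 - exp(-rate)),
    humped      = start + net_change * u + hump * 4 * u * (1 - u)
  ))
}

#' Define a synthetic species scenario
#'
#' A scenario bundles the biological attributes of one species (family,
#' maximum fork length, length-weight allometry \eqn{W = aL^b} on an
#' mm-to-kg basis) with the generating trajectories of its proportional
#' contribution to landings and its mean fork length.
#'
#' @param species_id,family Labels.
#' @param max_length_mm Maximum fork length (mm); individual lengths are
#'   truncated to `(0, max_length_mm]`.
#' @param lw_a,lw_b Allometric coefficient (kg, mm basis) and exponent;
#'   `lw_b` must lie in `[2.5, 3.5]`.
#' @param contribution_path [trend_spec()] on the proportion scale (values
#'   must stay non-negative; per-year proportions across a fishery's
#'   scenarios are renormalised to sum to 1).
#' @param size_path [trend_spec()] for the mean fork length (mm; must stay
#'   positive).
#' @param length_cv Coefficient of variation of individual lengths about the
#'   year's mean, in `(0, 0.5]`.
#' @param iconic Logical flag for large, iconic species tracked as a group.
#' @param lw_source_tier Provenance tier of the allometric coefficients
#'   (1 = local, 4 = other-Pacific).
#' @param sectors Optional character vector of geographic sectors to sample
#'   landings from (defaults to four island quadrants).
#' @return An object of class `species_scenario`.
#' @export
species_scenario <- function(species_id, family, max_length_mm, lw_a, lw_b,
                             contribution_path, size_path, length_cv = 0.15,
                             iconic = FALSE, lw_source_tier = 1L,
                             sectors = NULL) {
  stopifnot(inherits(contribution_path, "trend_spec"),
            inherits(size_path, "trend_spec"))
  if (!is.numeric(max_length_mm) || max_length_mm <= 0) {
    abort(sprintf("Scenario '%s': max_length_mm must be positive.", species_id))
  }
  if (lw_b < 2.5 || lw_b > 3.5) {
    abort(sprintf("Scenario '%s': lw_b must lie in [2.5, 3.5].", species_id))
  }
  if (length_cv <= 0 || length_cv > 0.5) {
    abort(sprintf("Scenario '%s': length_cv must lie in (0, 0.5].", species_id))
  }
  structure(
    list(species_id = species_id, family = family,
         max_length_mm = max_length_mm, lw_a = lw_a, lw_b = lw_b,
         contribution_path = contribution_path, size_path = size_path,
         length_cv = length_cv, iconic = isTRUE(iconic),
         lw_source_tier = as.integer(lw_source_tier), sectors = sectors),
    class = "species_scenario"
  )
}

#' Define an effort schedule
#'
#' The expected number of fish measured per year. Creel-survey reporting
#' effort is rarely constant — coverage typically decays late in a programme —
#' so `annual_n_fish` may vary by year; it is the source of the per-year
#' sample sizes that weighted trend regression exists to handle.
#'
#' @param years Integer vector of consecutive calendar years (length >= 4).
#' @param annual_n_fish Expected measured fish per year; scalar or one value
#'   per year. Must be non-negative.
#' @param seed RNG seed; the same seed yields an identical dataset.
#' @return An object of class `effort_schedule`.
#' @export
effort_schedule <- function(years, annual_n_fish, seed = 1L) {
  years <- as.integer(years)
  if (length(years) < 4L || any(diff(years) != 1L)) {
    abort("`years` must be >= 4 consecutive calendar years.")
  }
  if (length(annual_n_fish) == 1L) {
    annual_n_fish <- rep(annual_n_fish, length(years))
  }
  if (length(annual_n_fish) != length(years) || any(annual_n_fish < 0)) {
    abort("`annual_n_fish` must be non-negative, scalar or one value per year.")
  }
  structure(list(years = years, annual_n_fish = annual_n_fish,
                 seed = as.integer(seed)),
            class = "effort_schedule")
}

default_sectors <- c("north", "east", "south", "west")

path_values <- function(scenarios, which, n_years) {
  vapply(scenarios, function(sc) evaluate_path(sc[[which]], n_years),
         numeric(n_years))
}

validate_scenarios <- function(scenarios, n_years) {
  if (length(scenarios) == 0L) abort("At least one species scenario is required.")
  ok <- vapply(scenarios, inherits, logical(1), "species_scenario")
  if (!all(ok)) abort("All scenarios must be `species_scenario` objects.")
  for (sc in scenarios) {
    if (any(evaluate_path(sc$contribution_path, n_years) < 0)) {
      abort(sprintf("Scenario '%s': contribution path goes negative.", sc$species_id))
    }
    if (any(evaluate_path(sc$size_path, n_years) <= 0)) {
      abort(sprintf("Scenario '%s': size path must stay positive.", sc$species_id))
    }
  }
  invisible(scenarios)
}

# Truncated-normal lengths on (0, max_length], by inverse-CDF so the draw
# count per fish is fixed (helps seed-for-seed reproducibility).
draw_lengths <- function(n, mean, sd, max_length) {
  if (n == 0L) return(integer(0))
  if (sd <= 0) {
    len <- rep(mean, n)
  } else {
    lo <- stats::pnorm(0, mean, sd)
    hi <- stats::pnorm(max_length, mean, sd)
    u <- stats::runif(n, lo, hi)
    len <- stats::qnorm(u, mean, sd)
  }
  pmin(pmax(1L, as.integer(round(len))), as.integer(floor(max_length)))
}

#' Simulate creel-survey catch records
#'
#' Generates one landed-fish record per measured fish. Annual totals are
#' Poisson draws around the effort schedule; species counts within a year
#' are multinomial draws from the (renormalised) contribution paths; fork
#' lengths are truncated-normal draws about the year's size-path mean with
#' standard deviation `mean * length_cv`, rounded to the nearest mm.
#'
#' @param scenarios List of [species_scenario()] objects.
#' @param effort An [effort_schedule()].
#' @param fishery Fishery label stamped on every record (e.g. `"bottom"`).
#' @return A tibble with columns `year`, `fishery`, `sector`, `species`,
#'   `family`, `fork_length_mm`, `count` (always 1).
#' @export
#' @examples
#' eff <- effort_schedule(1990:1999, 100, seed = 7)
#' sc <- species_scenario("sp1", "famA", 500, 2e-8, 3,
#'                        trend_spec("constant", 1), trend_spec("linear", 300, -50))
#' simulate_catch(list(sc), eff, "bottom")
simulate_catch <- function(scenarios, effort, fishery = "bottom") {
  stopifnot(inherits(effort, "effort_schedule"))
  years <- effort$years
  n_years <- length(years)
  validate_scenarios(scenarios, n_years)

  contrib <- path_values(scenarios, "contribution_path", n_years)  # year x sp
  contrib <- matrix(contrib, nrow = n_years)
  sizes <- matrix(path_values(scenarios, "size_path", n_years), nrow = n_years)
  row_tot <- rowSums(contrib)
  if (any(row_tot <= 0)) abort("Contribution paths sum to zero in some year.")
  probs <- contrib / row_tot

  sp_ids <- vapply(scenarios, `[[`, character(1), "species_id")
  fams <- vapply(scenarios, `[[`, character(1), "family")
  cvs <- vapply(scenarios, `[[`, numeric(1), "length_cv")
  maxl <- vapply(scenarios, `[[`, numeric(1), "max_length_mm")

  local_seed(effort$seed, {
    out <- vector("list", n_years)
    for (i in seq_len(n_years)) {
      n_tot <- stats::rpois(1L, effort$annual_n_fish[i])
      counts <- if (n_tot > 0) {
        as.integer(stats::rmultinom(1L, n_tot, probs[i, ]))
      } else {
        integer(length(scenarios))
      }
      per_sp <- vector("list", length(scenarios))
      for (s in seq_along(scenarios)) {
        ns <- counts[s]
        if (ns == 0L) next
        mean_len <- sizes[i, s]
        lens <- draw_lengths(ns, mean_len, mean_len * cvs[s], maxl[s])
        secs <- scenarios[[s]]$sectors %||% default_sectors
        per_sp[[s]] <- tibble(
          year = years[i], fishery = fishery,
          sector = sample(secs, ns, replace = TRUE),
          species = sp_ids[s], family = fams[s],
          fork_length_mm = lens, count = 1L
        )
      }
      out[[i]] <- dplyr::bind_rows(per_sp)
    }
    dplyr::bind_rows(out)
  })
}

#' Ground truth for a scenario set
#'
#' Reports, per species and dependent variable, the generating trend form and
#' its signed net change (path value at the last year minus at the first);
#' used to score parameter- and classification-recovery on simulated data.
#' Contribution truth is on the raw (pre-normalisation) path scale.
#'
#' @inheritParams simulate_catch
#' @return A tibble with columns `species`, `family`, `variable`
#'   (`"contribution"` or `"size"`), `form`, `start`, `net_change`.
#' @export
scenario_truth <- function(scenarios, effort) {
  stopifnot(inherits(effort, "effort_schedule"))
  n_years <- length(effort$years)
  validate_scenarios(scenarios, n_years)
  purrr::map_dfr(scenarios, function(sc) {
    purrr::map_dfr(
      c(contribution = "contribution_path", size = "size_path"),
      function(fld) {
        v <- evaluate_path(sc[[fld]], n_years)
        tibble(form = sc[[fld]]$form, start = v[1],
               net_change = v[n_years] - v[1])
      },
      .id = "variable"
    ) |>
      mutate(species = sc$species_id, family = sc$family, .before = 1)
  })
}

#' Species attribute table implied by a scenario set
#'
#' @inheritParams simulate_catch
#' @return A tibble in the attributes-CSV schema (`species`, `family`,
#'   `lw_a`, `lw_b`, `lw_source_tier`, `max_length_mm`, `iconic`).
#' @export
scenario_attributes <- function(scenarios) {
  purrr::map_dfr(scenarios, function(sc) {
    tibble(species = sc$species_id, family = sc$family,
           lw_a = sc$lw_a, lw_b = sc$lw_b,
           lw_source_tier = sc$lw_source_tier,
           max_length_mm = sc$max_length_mm, iconic = sc$iconic)
  })
}

#' Read and write scenario files
#'
#' Scenario sets round-trip through YAML so that simulation settings are
#' plain-text and versionable.
#'
#' @param scenarios List of [species_scenario()] objects.
#' @param path File path.
#' @return `read_scenarios()` returns a list of `species_scenario` objects;
#'   `write_scenarios()` returns `path` invisibly.
#' @export
write_scenarios <- function(scenarios, path) {
  ser <- lapply(scenarios, function(sc) {
    sc <- unclass(sc)
    sc$contribution_path <- unclass(sc$contribution_path)
    sc$size_path <- unclass(sc$size_path)
    sc
  })
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(sc) {
    species_scenario(
      species_id = sc$species_id, family = sc$family,
      max_length_mm = sc$max_length_mm, lw_a = sc$lw_a, lw_b = sc$lw_b,
      contribution_path = do.call(trend_spec, sc$contribution_path),
      size_path = do.call(trend_spec, sc$size_path),
      length_cv = sc$length_cv, iconic = sc$iconic,
      lw_source_tier = sc$lw_source_tier,
      sectors = unlist(sc$sectors) %||% NULL
    )
  })
}

#' Scenario cohort with a planted mix of exploitation responses
#'
#' Builds a multi-family cohort of species scenarios whose generating trends
#' plant a known mix of management-category archetypes, for end-to-end
#' classification-recovery checks. Because percent contribution is measured
#' on biomass, a shrinking mean size alone would mechanically depress a
#' species' contribution; the archetypes therefore mirror the response types
#' seen in exploited reef fisheries:
#' \itemize{
#'   \item `size` — saturating (exponential) mean-size decline offset by a
#'     rising numeric contribution (compensatory recruitment), so the
#'     biomass share holds or grows while size structure erodes;
#'   \item `gear_quota_area` — numeric contribution fades out linearly at
#'     steady size (the species slowly leaves the fishery);
#'   \item `both_either` — comparable declines in both numbers and size;
#'   \item `none` — both variables steady.
#' }
#' The linear count paths are balanced across archetypes so the cohort's
#' total raw contribution stays constant each year: after normalisation,
#' steady species really are steady. Families are tiers of adjacent maximum
#' lengths, keeping every species above the within-family 1-percent biomass
#' filter.
#'
#' @param n_species Cohort size.
#' @param mix Named proportions for `size`, `gear_quota_area`,
#'   `both_either`, `none`; must sum to 1.
#' @param n_families Number of families (size tiers) the cohort spans.
#' @param length_cv Individual-length coefficient of variation.
#' @return A list with `scenarios` (a list of [species_scenario()]) and
#'   `truth` (a tibble `species, true_category`).
#' @export
recovery_cohort <- function(n_species = 40,
                            mix = c(size = 0.4, gear_quota_area = 0.2,
                                    both_either = 0.1, none = 0.3),
                            n_families = 4, length_cv = 0.15) {
  stopifnot(abs(sum(mix) - 1) < 1e-9,
            setequal(names(mix), c("size", "gear_quota_area", "both_either", "none")))
  counts <- round(n_species * mix[c("size", "gear_quota_area", "both_either", "none")])
  counts[["none"]] <- n_species - sum(counts[c("size", "gear_quota_area", "both_either")])
  cats <- rep(names(counts), counts)
  # count-path endpoints per archetype; increases (size archetype) balance
  # the declines so the cohort total is constant through time
  path_start <- c(size = 0.020, gear_quota_area = 0.060,
                  both_either = 0.040, none = 0.025)
  rise_per_sp <- (counts[["gear_quota_area"]] * 0.050 +
                    counts[["both_either"]] * 0.020) /
    max(counts[["size"]], 1L)
  path_net <- c(size = rise_per_sp, gear_quota_area = -0.050,
                both_either = -0.020, none = 0)
  fam_size <- ceiling(n_species / n_families)
  scenarios <- vector("list", n_species)
  truth <- tibble(species = sprintf("sp%02d", seq_len(n_species)),
                  true_category = cats)
  for (i in seq_len(n_species)) {
    fam_idx <- (i - 1L) %/% fam_size + 1L
    pos <- (i - 1L) %% fam_size + 1L
    maxl <- 240 + 160 * (fam_idx - 1L) + 15 * pos
    s0 <- 0.72 * maxl
    cat_i <- cats[i]
    contribution <- trend_spec(
      if (path_net[[cat_i]] == 0) "constant" else "linear",
      path_start[[cat_i]], path_net[[cat_i]]
    )
    size <- switch(cat_i,
      size = trend_spec("exponential", s0, -0.22 * s0),
      both_either = trend_spec("linear", s0, -0.20 * s0),
      trend_spec("constant", s0)
    )
    scenarios[[i]] <- species_scenario(
      truth$species[i], paste0("fam", fam_idx), maxl, lw_a = 2e-8, lw_b = 3,
      contribution_path = contribution, size_path = size,
      length_cv = length_cv
    )
  }
  list(scenarios = scenarios, truth = truth)
}
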