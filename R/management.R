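#' Assign a potential management category to one species
#'
#' Applies a four-criterion decision rule to the selected trend models of a
#' species' mean-size and percent-contribution series:
#' \enumerate{
#'   \item Asymptotic (exponential/power) or polynomial models with an
#'     immediate decline (negative fitted derivative at the first timestep)
#'     outrank linear models. If only one variable declines, or one declines
#'     under a stronger model class, that variable decides: a size decline
#'     maps to `"size"` (size-based policies), a contribution decline to
#'     `"gear_quota_area"` (the species fades from the fishery).
#'   \item With equally strong models for both declines, standardised effect
#'     sizes are compared; non-overlapping +/-1 SE intervals give the
#'     category of the larger-magnitude response.
#'   \item Overlapping effect sizes give `"both_either"`.
#'   \item Species with no significant declining response (including
#'     significant increases) get `"none"`.
#' }
#' A significant increase in one variable never blocks classification by a
#' decline in the other.
#'
#' @param size_fit,contribution_fit Selected `creel_fit` objects (or `NULL`
#'   when no model was selected) for the species' mean-size and
#'   percent-contribution series.
#' @param effect_metric `"std_slope"` (standardised slope and its SE) or
#'   `"net_change_frac"` (fractional net change, SE scaled from the slope's
#'   relative SE).
#' @param se_mult Half-width multiplier of the effect-size interval (1 =
#'   literal +/-1 standard error).
#' @return A list with `category` (one of `"size"`, `"gear_quota_area"`,
#'   `"both_either"`, `"none"`) and `rationale` (the criterion index 1-4
#'   that resolved the assignment).
#' @export
classify_species <- function(size_fit, contribution_fit,
                             effect_metric = c("std_slope", "net_change_frac"),
                             se_mult = 1) {
  effect_metric <- match.arg(effect_metric)
  declining <- function(f) {
    !is.null(f) && is.finite(f$net_change) && f$net_change < 0
  }
  strong <- function(f) {
    f$form %in% c("exponential", "power", "quadratic") && f$deriv_first < 0
  }
  effect_mag <- function(f) {
    if (effect_metric == "std_slope") {
      c(m = abs(f$effect), se = f$effect_se)
    } else {
      slope <- f$coefficients$estimate[2L]
      rel_se <- f$coefficients$std.error[2L] / abs(slope)
      m <- abs(f$net_change_pct) / 100
      c(m = m, se = m * rel_se)
    }
  }

  s_dec <- declining(size_fit)
  c_dec <- declining(contribution_fit)
  if (!s_dec && !c_dec) {
    return(list(category = "none", rationale = 4L))
  }
  if (s_dec && !c_dec) return(list(category = "size", rationale = 1L))
  if (!s_dec && c_dec) return(list(category = "gear_quota_area", rationale = 1L))

  s_strong <- strong(size_fit)
  c_strong <- strong(contribution_fit)
  if (s_strong != c_strong) {
    return(list(category = if (s_strong) "size" else "gear_quota_area",
                rationale = 1L))
  }
  es <- effect_mag(size_fit)
  ec <- effect_mag(contribution_fit)
  if (es[["m"]] - se_mult * es[["se"]] > ec[["m"]] + se_mult * ec[["se"]]) {
    return(list(category = "size", rationale = 2L))
  }
  if (ec[["m"]] - se_mult * ec[["se"]] > es[["m"]] + se_mult * es[["se"]]) {
    return(list(category = "gear_quota_area", rationale = 2L))
  }
  list(category = "both_either", rationale = 3L)
}

#' Classify every assessed species from fitted trends
#'
#' Pairs each species' `species_size` and `species_contribution` fits within
#' a fishery and applies [classify_species()].
#'
#' @param fits Output of [fit_trends()].
#' @param config A [creel_config()] (supplies `effect_metric`).
#' @return A tibble `fishery, species, category, rationale` plus per-variable
#'   summary columns (`size_form`, `size_r2`, `size_p`, `size_net_pct`,
#'   `contribution_form`, `contribution_r2`, `contribution_p`,
#'   `contribution_net_pct`).
#' @export
classify_management <- function(fits, config = creel_config()) {
  sp_fits <- fits |>
    filter(.data$variable %in% c("species_size", "species_contribution"))
  if (nrow(sp_fits) == 0L) {
    abort("No species-level series in `fits`; run build_series()/fit_trends() first.")
  }
  sp_fits |>
    group_by(.data$fishery, species = .data$group) |>
    group_modify(function(df, key) {
      pick <- function(v) {
        row <- df |> filter(.data$variable == v)
        if (nrow(row) == 1L && row$selected[[1L]]) row$fit[[1L]] else NULL
      }
      stat <- function(v, col) {
        row <- df |> filter(.data$variable == v)
        if (nrow(row) == 1L) row[[col]][[1L]] else NA
      }
      sz <- pick("species_size")
      ct <- pick("species_contribution")
      cl <- classify_species(sz, ct, effect_metric = config$effect_metric)
      tibble(
        category = cl$category, rationale = cl$rationale,
        size_form = stat("species_size", "form"),
        size_r2 = stat("species_size", "r2"),
        size_p = stat("species_size", "p_value"),
        size_net_pct = stat("species_size", "net_change_pct"),
        contribution_form = stat("species_contribution", "form"),
        contribution_r2 = stat("species_contribution", "r2"),
        contribution_p = stat("species_contribution", "p_value"),
        contribution_net_pct = stat("species_contribution", "net_change_pct")
      )
    }) |>
    ungroup()
}

#' Summarise management assignments
#'
#' @param assignments Output of [classify_management()].
#' @return A list with `by_fishery` and `overall` tibbles (species assessed,
#'   species placed into a category, placed fraction, and per-category
#'   proportions among placed species) and `consistency` (species assessed
#'   in several fisheries, with whether their categories agree).
#' @export
summarize_management <- function(assignments) {
  if (nrow(assignments) == 0L) abort("No assignments to summarise.")
  tally_one <- function(df) {
    placed <- df |> filter(.data$category != "none")
    tibble(
      n_assessed = nrow(df), n_placed = nrow(placed),
      placed_fraction = nrow(placed) / nrow(df),
      prop_size = mean(placed$category == "size"),
      prop_gear_quota_area = mean(placed$category == "gear_quota_area"),
      prop_both_either = mean(placed$category == "both_either")
    )
  }
  by_fishery <- assignments |>
    group_by(.data$fishery) |>
    group_modify(~ tally_one(.x)) |>
    ungroup()
  overall <- tally_one(assignments)
  consistency <- assignments |>
    filter(.data$category != "none") |>
    group_by(.data$species) |>
    filter(dplyr::n() > 1L) |>
    summarise(n_fisheries = dplyr::n(),
              consistent = dplyr::n_distinct(.data$category) == 1L,
              .groups = "drop")
  list(by_fishery = by_fishery, overall = overall, consistency = consistency)
}

#' Write a per-species management table as CSV
#'
#' One row per assessed species in the style of a published species table:
#' sample size, proportional biomass, R-squared with significance stars for
#' the size and contribution trends, and the potential management category.
#'
#' @param assignments Output of [classify_management()].
#' @param records Filtered catch records with `biomass_kg` (for sample sizes
#'   and biomass shares).
#' @param path Output file path.
#' @return The table written, invisibly.
#' @export
write_species_table <- function(assignments, records, path) {
  shares <- records |>
    group_by(.data$fishery, .data$species) |>
    summarise(n = sum(.data$count), kg = sum(.data$biomass_kg), .groups = "drop_last") |>
    mutate(proportional_biomass_pct = 100 * .data$kg / sum(.data$kg)) |>
    ungroup()
  tab <- assignments |>
    left_join(shares, by = c("fishery", "species")) |>
    mutate(
      size_r2_stars = ifelse(is.na(.data$size_r2), "",
                             sprintf("%.2f%s", .data$size_r2, p_stars(.data$size_p))),
      contribution_r2_stars = ifelse(
        is.na(.data$contribution_r2), "",
        sprintf("%.2f%s", .data$contribution_r2, p_stars(.data$contribution_p))),
      potential_management = dplyr::recode(.data$category,
        size = "size", gear_quota_area = "gear/quota/area",
        both_either = "both/either", none = "")
    ) |>
    arrange(.data$fishery, dplyr::desc(.data$proportional_biomass_pct)) |>
    select("fishery", "species", "n", "proportional_biomass_pct",
           "size_r2_stars", "contribution_r2_stars", "potential_management")
  readr::write_csv(tab, path, na = "")
  invisible(tab)
}
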