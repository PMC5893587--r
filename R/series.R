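#' Build smoothed annual dependent-variable series for each fishery
#'
#' Emits, per fishery, the hierarchy of dependent variables analysed for
#' exploitation trends:
#' \itemize{
#'   \item `family_contribution` — percent of annual landed biomass per
#'     dominant family (families above `dominance_pct` of the fishery's
#'     total biomass);
#'   \item `family_ratio` — large:small biomass ratio per dominant family
#'     with a valid body-size classification;
#'   \item `other_mean_size` — mean fork length of all fish outside the
#'     dominant families ("other fishes");
#'   \item `iconic_contribution` — percent of annual biomass from large,
#'     iconic species, pooled;
#'   \item `species_contribution`, `species_size` — per-species percent
#'     contribution and mean size, for the top species cumulatively reaching
#'     `coverage_pct` of fishery biomass with at least `min_n` measured fish.
#' }
#' Percent-contribution series are computed on biomass (kg). Values are
#' smoothed with a centred moving average ([moving_average()]); raw values
#' are retained. Weights carry per-year confidence: total landed kg for
#' biomass-derived variables, measured-fish counts for size variables.
#' Years inside a fishery's span with no relevant records get missing values
#' and zero weight. Series with fewer than 5 usable years are emitted but
#' flagged unfittable.
#'
#' @param records Filtered catch records with `biomass_kg`.
#' @param classification Output of [classify_sizes()] (used for the ratio
#'   series); may be `NULL` to skip ratios.
#' @param attributes Species-attributes tibble (supplies the `iconic` flag).
#' @param config A [creel_config()].
#' @return A tibble `fishery, variable, group, year, raw, smoothed, weight,
#'   fittable`.
#' @export
build_series <- function(records, classification = NULL, attributes = NULL,
                         config = creel_config()) {
  stopifnot(inherits(config, "creel_config"))
  iconic_sp <- if (!is.null(attributes) && "iconic" %in% names(attributes)) {
    attributes$species[which(attributes$iconic)]
  } else {
    character()
  }

  per_fishery <- records |>
    group_by(.data$fishery) |>
    group_map(function(df, key) {
      build_series_one(df, key$fishery, classification, iconic_sp, config)
    })
  out <- dplyr::bind_rows(per_fishery)
  out |>
    arrange(.data$fishery, .data$variable, .data$group, .data$year) |>
    group_by(.data$fishery, .data$variable, .data$group) |>
    mutate(
      smoothed = moving_average(.data$raw, config$window),
      fittable = sum(is.finite(.data$raw) & .data$weight > 0) >= 5L
    ) |>
    ungroup()
}

build_series_one <- function(df, fishery, classification, iconic_sp, config) {
  df$fishery <- fishery
  years <- seq(min(df$year), max(df$year))
  grid <- tibble(year = years)
  annual_tot <- df |>
    group_by(.data$year) |>
    summarise(tot_kg = sum(.data$biomass_kg), .groups = "drop") |>
    right_join(grid, by = "year") |>
    mutate(tot_kg = tidyr::replace_na(.data$tot_kg, 0)) |>
    arrange(.data$year)

  fam_tot <- df |>
    group_by(.data$family) |>
    summarise(kg = sum(.data$biomass_kg), .groups = "drop") |>
    mutate(share_pct = 100 * .data$kg / sum(.data$kg))
  dominant <- fam_tot$family[fam_tot$share_pct > config$dominance_pct]

  pct_series <- function(sub, group, variable) {
    ann <- sub |>
      group_by(.data$year) |>
      summarise(kg = sum(.data$biomass_kg), .groups = "drop") |>
      right_join(annual_tot, by = "year") |>
      arrange(.data$year) |>
      mutate(kg = tidyr::replace_na(.data$kg, 0),
             raw = ifelse(.data$tot_kg > 0, 100 * .data$kg / .data$tot_kg, NA_real_))
    tibble(fishery = fishery, variable = variable, group = group,
           year = ann$year, raw = ann$raw, weight = ann$tot_kg)
  }
  size_series <- function(sub, group, variable) {
    ann <- sub |>
      group_by(.data$year) |>
      summarise(raw = stats::weighted.mean(.data$fork_length_mm, .data$count),
                n_fish = sum(.data$count), .groups = "drop") |>
      right_join(grid, by = "year") |>
      arrange(.data$year) |>
      mutate(n_fish = tidyr::replace_na(.data$n_fish, 0))
    tibble(fishery = fishery, variable = variable, group = group,
           year = ann$year, raw = ann$raw, weight = as.numeric(ann$n_fish))
  }

  parts <- list()
  for (fam in dominant) {
    parts[[paste0("famc_", fam)]] <-
      pct_series(df |> filter(.data$family == fam), fam, "family_contribution")
  }

  if (!is.null(classification) && length(dominant)) {
    ok_fams <- classification |>
      filter(.data$status == "ok", .data$family %in% dominant) |>
      distinct(.data$family)
    if (nrow(ok_fams)) {
      ratios <- large_small_ratio(df |> filter(.data$family %in% ok_fams$family),
                                  classification)
      for (fam in unique(ratios$family)) {
        r <- ratios |>
          filter(.data$family == fam) |>
          right_join(grid, by = "year") |>
          arrange(.data$year) |>
          mutate(weight_kg = tidyr::replace_na(.data$weight_kg, 0))
        parts[[paste0("famr_", fam)]] <- tibble(
          fishery = fishery, variable = "family_ratio", group = fam,
          year = r$year, raw = r$ratio,
          weight = ifelse(is.finite(r$ratio), r$weight_kg, 0)
        )
      }
    }
  }

  other <- df |> filter(!.data$family %in% dominant)
  if (nrow(other)) {
    parts$other <- size_series(other, "other", "other_mean_size")
  }

  iconic <- df |> filter(.data$species %in% iconic_sp)
  if (nrow(iconic)) {
    parts$iconic <- pct_series(iconic, "iconic", "iconic_contribution")
  }

  sp_rank <- df |>
    group_by(.data$species) |>
    summarise(kg = sum(.data$biomass_kg), n_fish = sum(.data$count),
              .groups = "drop") |>
    arrange(dplyr::desc(.data$kg)) |>
    mutate(cum_pct = 100 * cumsum(.data$kg) / sum(.data$kg))
  n_top <- which(sp_rank$cum_pct >= config$coverage_pct)[1L]
  if (is.na(n_top)) n_top <- nrow(sp_rank)
  top_sp <- sp_rank |>
    dplyr::slice_head(n = n_top) |>
    filter(.data$n_fish >= config$min_n)
  for (sp in top_sp$species) {
    sub <- df |> filter(.data$species == sp)
    parts[[paste0("spc_", sp)]] <- pct_series(sub, sp, "species_contribution")
    parts[[paste0("sps_", sp)]] <- size_series(sub, sp, "species_size")
  }

  dplyr::bind_rows(parts)
}

#' Fit and select trend models for every series
#'
#' Maps [fit_candidates()] and [select_model()] over each series produced by
#' [build_series()], fitting the smoothed values against the year index with
#' the series' confidence weights.
#'
#' @param series Tibble from [build_series()].
#' @param config A [creel_config()] (supplies `alpha`).
#' @return One row per series: identifiers, `n_years`, `fittable`, the
#'   selected model's summary columns (`form`, `equation`, `r2`, `p_value`,
#'   `aic`, `shapiro_p`, `dw`, `net_change`, `net_change_pct`, `effect`,
#'   `effect_se`, `flags`), `selected` (whether any model passed), and
#'   list-columns `fit` (the selected `creel_fit` or `NULL`) and
#'   `candidates` (all fitted forms).
#' @export
fit_trends <- function(series, config = creel_config()) {
  series |>
    group_by(.data$fishery, .data$variable, .data$group) |>
    group_modify(function(df, key) {
      df <- df |> arrange(.data$year)
      usable <- sum(is.finite(df$smoothed) & df$weight > 0)
      base <- tibble(
        n_years = nrow(df), fittable = usable >= 5L,
        selected = FALSE, form = NA_character_, equation = NA_character_,
        r2 = NA_real_, p_value = NA_real_, aic = NA_real_,
        shapiro_p = NA_real_, dw = NA_real_,
        net_change = NA_real_, net_change_pct = NA_real_,
        effect = NA_real_, effect_se = NA_real_, flags = "",
        fit = list(NULL), candidates = list(list())
      )
      if (usable < 5L) {
        warn(sprintf("Series %s/%s/%s has %d usable years; not fitted.",
                     key$fishery, key$variable, key$group, usable))
        return(base)
      }
      x <- seq_len(nrow(df))
      cand <- fit_candidates(df$smoothed, weights = df$weight, x = x)
      best <- select_model(cand, alpha = config$alpha)
      base$candidates <- list(cand)
      if (is.null(best)) return(base)
      base |>
        mutate(
          selected = TRUE, form = best$form, equation = equation_string(best),
          r2 = best$r2, p_value = best$p_value, aic = best$aic,
          shapiro_p = best$shapiro_p, dw = best$dw,
          net_change = best$net_change, net_change_pct = best$net_change_pct,
          effect = best$effect, effect_se = best$effect_se,
          flags = paste(best$flags, collapse = ","),
          fit = list(best)
        )
    }) |>
    ungroup()
}

#' Write trend fits as a compact CSV
#'
#' One row per series with the selected model's equation string (2
#' significant digits), R-squared with significance stars, AIC and flags.
#'
#' @param fits Output of [fit_trends()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  fits |>
    mutate(r2_stars = ifelse(is.na(.data$r2), "",
                             sprintf("%.2f%s", .data$r2, p_stars(.data$p_value)))) |>
    select("fishery", "variable", "group", "form", "equation",
           "r2_stars", "aic", "net_change_pct", "flags") |>
    readr::write_csv(path, na = "")
  invisible(path)
}
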