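#' Read catch records and species attributes
#'
#' Catch CSVs carry one row per measured fish (or species-size batch):
#' `year, fishery, sector, species, family, fork_length_mm, count`.
#' Attribute CSVs carry one row per species:
#' `species, family, lw_a, lw_b, lw_source_tier, max_length_mm, iconic`.
#'
#' Length-weight coefficients may be published on several unit bases; the
#' `basis` argument declares the basis of the file once and the table is
#' converted internally to mm-to-kg, avoiding the classic `10^b` unit error.
#' When several coefficient rows exist for one species, the row with the
#' best (lowest) provenance tier is retained.
#'
#' @param path CSV file path.
#' @param basis Unit basis of `lw_a` in the file: `"mm_kg"` (default),
#'   `"mm_g"`, or `"cm_g"`.
#' @return A tibble.
#' @export
read_catch_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), fishery = readr::col_character(),
    sector = readr::col_character(), species = readr::col_character(),
    family = readr::col_character(), fork_length_mm = readr::col_double(),
    count = readr::col_integer()
  ))
}

#' @rdname read_catch_csv
#' @param records Catch-record tibble.
#' @export
write_catch_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' @rdname read_catch_csv
#' @export
read_attributes_csv <- function(path, basis = c("mm_kg", "mm_g", "cm_g")) {
  basis <- match.arg(basis)
  attrs <- readr::read_csv(path, col_types = readr::cols(
    species = readr::col_character(), family = readr::col_character(),
    lw_a = readr::col_double(), lw_b = readr::col_double(),
    lw_source_tier = readr::col_integer(),
    max_length_mm = readr::col_double(), iconic = readr::col_logical()
  ))
  bad_tier <- !attrs$lw_source_tier %in% 1:4
  if (any(bad_tier)) {
    abort(paste0("lw_source_tier must be in 1..4 for: ",
                 paste(unique(attrs$species[bad_tier]), collapse = ", ")))
  }
  attrs$lw_a <- switch(basis,
    mm_kg = attrs$lw_a,
    mm_g  = attrs$lw_a / 1000,
    cm_g  = attrs$lw_a / (1000 * 10^attrs$lw_b)
  )
  attrs |>
    arrange(.data$species, .data$lw_source_tier) |>
    distinct(.data$species, .keep_all = TRUE)
}

reason_levels <- c("out_of_region", "missing_attributes", "invalid_measurement",
                   "family<1%", "species<1%")

#' Apply the study's exclusion filters to catch records
#'
#' Filters are applied in a fixed order so that the percentage bases are
#' well defined:
#' \enumerate{
#'   \item location — records from configured out-of-region sectors;
#'   \item validity — records with no species attributes (error in strict
#'     mode), non-positive fork lengths, or lengths above
#'     `max_length_mm * length_tolerance`;
#'   \item family — families contributing `< family_pct` percent of the total
#'     landed biomass (pooled across fisheries by default);
#'   \item species — species contributing `< species_pct` percent of their
#'     family's landed biomass.
#' }
#' Thresholds are strict inequalities: a family or species at exactly the
#' threshold share is kept. Biomass (kg) is attached to every record via the
#' allometric conversion before the share-based filters run, and the filter
#' report reconciles record counts and mass exactly (records whose biomass
#' cannot be computed carry zero mass in the accounting).
#'
#' @param records Catch-record tibble.
#' @param attributes Species-attributes tibble (mm-to-kg basis).
#' @param config A [creel_config()].
#' @return The retained records (with a `biomass_kg` column), with the filter
#'   report attached as attribute `"filter_report"`; retrieve it with
#'   [filter_report()].
#' @export
apply_filters <- function(records, attributes, config = creel_config()) {
  stopifnot(inherits(config, "creel_config"))
  if (nrow(records) == 0L) abort("`records` is empty.")

  attrs <- attributes |>
    arrange(.data$species, .data$lw_source_tier) |>
    distinct(.data$species, .keep_all = TRUE)

  rec <- records |>
    select(-dplyr::any_of(c("family", "biomass_kg"))) |>
    left_join(attrs |>
                select("species", "family", "lw_a", "lw_b", "max_length_mm"),
              by = "species") |>
    mutate(
      biomass_kg = ifelse(
        !is.na(.data$lw_a) & !is.na(.data$fork_length_mm) & .data$fork_length_mm > 0,
        .data$count * .data$lw_a * .data$fork_length_mm^.data$lw_b,
        0
      )
    )

  n_in <- nrow(rec)
  mass_in <- sum(rec$biomass_kg)
  drop_rec <- list()
  note_drop <- function(df, reason) {
    if (nrow(df) == 0L) return(NULL)
    tibble(reason = reason, n = nrow(df), mass_kg = sum(df$biomass_kg))
  }

  # (iii) location
  out_region <- rec$sector %in% config$out_of_region_sectors
  drop_rec$location <- note_drop(rec[out_region, ], "out_of_region")
  rec <- rec[!out_region, ]

  # validity: unmatched species, then measurement errors
  unmatched <- is.na(rec$lw_a)
  if (any(unmatched) && isTRUE(config$strict)) {
    abort(paste0("No attributes for species: ",
                 paste(sort(unique(rec$species[unmatched])), collapse = ", ")))
  }
  drop_rec$unmatched <- note_drop(rec[unmatched, ], "missing_attributes")
  rec <- rec[!unmatched, ]
  invalid <- is.na(rec$fork_length_mm) | rec$fork_length_mm <= 0 |
    rec$fork_length_mm > rec$max_length_mm * config$length_tolerance
  drop_rec$invalid <- note_drop(rec[invalid, ], "invalid_measurement")
  rec <- rec[!invalid, ]

  # (i) family share of overall biomass
  fam_share <- rec |>
    group_by(dplyr::across(dplyr::any_of(
      if (isTRUE(config$family_filter_per_fishery)) c("fishery", "family") else "family"
    ))) |>
    summarise(mass_kg = sum(.data$biomass_kg), n = dplyr::n(), .groups = "drop_last") |>
    mutate(share_pct = 100 * .data$mass_kg / sum(.data$mass_kg)) |>
    ungroup()
  fam_drop <- fam_share |> filter(.data$share_pct < config$family_pct)
  if (nrow(fam_drop)) {
    key <- if (isTRUE(config$family_filter_per_fishery)) c("fishery", "family") else "family"
    dropped <- dplyr::semi_join(rec, fam_drop, by = key)
    drop_rec$family <- note_drop(dropped, "family<1%")
    rec <- dplyr::anti_join(rec, fam_drop, by = key)
  }

  # (ii) species share within family biomass
  sp_share <- rec |>
    group_by(.data$family, .data$species) |>
    summarise(mass_kg = sum(.data$biomass_kg), n = dplyr::n(), .groups = "drop_last") |>
    mutate(share_pct = 100 * .data$mass_kg / sum(.data$mass_kg)) |>
    ungroup()
  sp_drop <- sp_share |> filter(.data$share_pct < config$species_pct)
  if (nrow(sp_drop)) {
    dropped <- dplyr::semi_join(rec, sp_drop, by = c("family", "species"))
    drop_rec$species <- note_drop(dropped, "species<1%")
    rec <- dplyr::anti_join(rec, sp_drop, by = c("family", "species"))
  }

  dropped_records <- dplyr::bind_rows(drop_rec)
  if (nrow(dropped_records) == 0L) {
    dropped_records <- tibble(reason = character(), n = integer(), mass_kg = numeric())
  }
  report <- structure(list(
    n_records_in = n_in, n_records_out = nrow(rec),
    mass_in_kg = mass_in, mass_out_kg = sum(rec$biomass_kg),
    n_species_out = dplyr::n_distinct(rec$species),
    dropped_records = dropped_records,
    dropped_families = fam_drop |> mutate(reason = "family<1%"),
    dropped_species = sp_drop |> mutate(reason = "species<1%")
  ), class = "filter_report")

  rec <- rec |> select(-"lw_a", -"lw_b", -"max_length_mm")
  attr(rec, "filter_report") <- report
  rec
}

#' Retrieve the filter report attached by [apply_filters()]
#'
#' @param records The tibble returned by [apply_filters()].
#' @return A `filter_report` object.
#' @export
filter_report <- function(records) {
  rep <- attr(records, "filter_report")
  if (is.null(rep)) abort("No filter report attached; run apply_filters() first.")
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d -> %d records, %.3f -> %.3f kg\n",
              x$n_records_in, x$n_records_out, x$mass_in_kg, x$mass_out_kg))
  if (nrow(x$dropped_records)) {
    for (i in seq_len(nrow(x$dropped_records))) {
      cat(sprintf("  dropped %d records (%.3f kg): %s\n",
                  x$dropped_records$n[i], x$dropped_records$mass_kg[i],
                  x$dropped_records$reason[i]))
    }
  } else {
    cat("  nothing dropped\n")
  }
  invisible(x)
}

#' Write a filter report as JSON
#'
#' @param report A `filter_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Determine each fishery's analysis timeframe
#'
#' A fishery is analysed over the longest contiguous run of years whose
#' centred rolling mean of annual reported biomass meets a minimum
#' (endpoints use the truncated available window). Ties between equally long
#' runs are broken toward the earlier run; years with no records count as
#' zero landings.
#'
#' @param records Catch records with a `biomass_kg` column.
#' @param threshold_kg Minimum rolling-average annual landings (kg/yr).
#' @param window Rolling-mean window (odd).
#' @return A tibble `fishery, start_year, end_year, n_years` (`NA` years and
#'   `n_years = 0` when no run qualifies).
#' @export
fishery_timeframe <- function(records, threshold_kg = 50, window = 3) {
  window <- check_window(window)
  if (!"biomass_kg" %in% names(records)) {
    abort("`records` needs a `biomass_kg` column (see apply_filters()/add_biomass()).")
  }
  records |>
    group_by(.data$fishery) |>
    group_modify(function(df, key) {
      yrs <- seq(min(df$year), max(df$year))
      kg <- vapply(yrs, function(y) sum(df$biomass_kg[df$year == y]), numeric(1))
      pass <- ma_truncated(kg, window) >= threshold_kg
      runs <- rle(pass)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      ok <- which(runs$values)
      if (length(ok) == 0L) {
        return(tibble(start_year = NA_integer_, end_year = NA_integer_,
                      n_years = 0L))
      }
      best <- ok[which.max(runs$lengths[ok])]  # ties -> earliest
      tibble(start_year = yrs[starts[best]], end_year = yrs[ends[best]],
             n_years = runs$lengths[best])
    }) |>
    ungroup()
}
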