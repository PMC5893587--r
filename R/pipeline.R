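#' Run the full trend-analysis pipeline
#'
#' Orchestrates the analysis end-to-end: load (or simulate) catch records,
#' apply the exclusion filters, restrict each fishery to its analysis
#' timeframe, classify body sizes, build the dependent-variable series, fit
#' and select trend models, classify species into potential management
#' categories, and summarise. Deterministic given `config$seed`.
#'
#' @param config A [creel_config()].
#' @param catch Catch records: a tibble, a CSV path, or `NULL` to simulate
#'   from `scenarios`.
#' @param attributes Species attributes: a tibble or CSV path; defaults to
#'   the attributes implied by `scenarios` when simulating.
#' @param scenarios A list of [species_scenario()] objects or a YAML path
#'   (used when `catch` is `NULL`).
#' @param effort An [effort_schedule()] (required when simulating). Its seed
#'   is overridden by `config$seed` when the latter is set.
#' @param out_dir Optional directory; when given, the filter report (JSON),
#'   size classification, trend fits and species tables (CSV), and a summary
#'   JSON are written there (plus one PDF of per-series plots when
#'   `plots = TRUE`).
#' @param plots Write per-series plots (courtesy output).
#' @return An object of class `creel_run`: a list with `records`,
#'   `filter_report`, `timeframes`, `size_classes`, `series`, `fits`,
#'   `assignments`, `summary`, `config`.
#' @export
run_pipeline <- function(config = creel_config(), catch = NULL,
                         attributes = NULL, scenarios = NULL, effort = NULL,
                         out_dir = NULL, plots = FALSE) {
  stopifnot(inherits(config, "creel_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  if (is.character(scenarios)) scenarios <- read_scenarios(scenarios)
  if (is.null(catch)) {
    if (is.null(scenarios) || is.null(effort)) {
      abort("Provide `catch`, or `scenarios` plus `effort` to simulate.")
    }
    if (!is.null(config$seed)) effort$seed <- as.integer(config$seed)
    catch <- stage("simulate", simulate_catch(scenarios, effort))
  } else if (is.character(catch)) {
    catch <- stage("read_catch", read_catch_csv(catch))
  }
  if (is.null(attributes)) {
    if (is.null(scenarios)) abort("`attributes` required when not simulating.")
    attributes <- scenario_attributes(scenarios)
  } else if (is.character(attributes)) {
    attributes <- stage("read_attributes", read_attributes_csv(attributes))
  }

  filtered <- stage("filter", apply_filters(catch, attributes, config))
  freport <- filter_report(filtered)

  timeframes <- stage("timeframe",
    fishery_timeframe(filtered, config$timeframe_kg, config$window))
  filtered <- filtered |>
    inner_join(timeframes |> filter(.data$n_years > 0L), by = "fishery") |>
    filter(.data$year >= .data$start_year, .data$year <= .data$end_year) |>
    select(-"start_year", -"end_year", -"n_years")
  if (nrow(filtered) == 0L) {
    abort("Pipeline stage 'timeframe' failed: no fishery meets the landings threshold.")
  }

  retained_attrs <- attributes |> filter(.data$species %in% filtered$species)
  size_classes <- stage("classify_sizes",
    classify_sizes(retained_attrs, increment = config$gvf_increment))
  series <- stage("build_series",
    build_series(filtered, size_classes, attributes, config))
  fits <- stage("fit_trends", fit_trends(series, config))
  assignments <- stage("classify_management", classify_management(fits, config))
  summary <- stage("summarize", summarize_management(assignments))

  run <- structure(list(
    records = filtered, filter_report = freport, timeframes = timeframes,
    size_classes = size_classes, series = series, fits = fits,
    assignments = assignments, summary = summary, config = config
  ), class = "creel_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_filter_report(freport, file.path(out_dir, "filter_report.json"))
    write_classification_csv(size_classes, file.path(out_dir, "size_classes.csv"))
    write_fits_csv(fits, file.path(out_dir, "trend_fits.csv"))
    write_species_table(assignments, filtered,
                        file.path(out_dir, "species_tables.csv"))
    jsonlite::write_json(
      list(by_fishery = summary$by_fishery, overall = summary$overall,
           consistency = summary$consistency),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (isTRUE(plots)) {
      grDevices::pdf(file.path(out_dir, "series_plots.pdf"), width = 7, height = 4)
      on.exit(grDevices::dev.off(), add = TRUE)
      keys <- fits |> distinct(.data$fishery, .data$variable, .data$group)
      for (i in seq_len(nrow(keys))) {
        print(plot_trend(run, keys$fishery[i], keys$variable[i], keys$group[i]))
      }
    }
  }
  run
}

#' @export
print.creel_run <- function(x, ...) {
  cat("<creel_run>\n")
  print(x$filter_report)
  cat(sprintf("  %d series built, %d with a selected model\n",
              nrow(x$fits), sum(x$fits$selected)))
  cat(sprintf("  %d species assessed, %.0f%% placed into a management category\n",
              x$summary$overall$n_assessed,
              100 * x$summary$overall$placed_fraction))
  invisible(x)
}

#' Plot one dependent-variable series with its selected trend model
#'
#' Points are the smoothed annual values, scaled by the per-year confidence
#' weight used in the regression. A fitted line with a confidence band is
#' drawn only when a model was selected for the series. An optional vertical
#' line marks a fishery-expansion year.
#'
#' @param run A `creel_run` from [run_pipeline()], or a list with `series`
#'   and `fits` tibbles.
#' @param fishery,variable,group Series identifiers.
#' @param expansion_year Year to annotate; defaults to
#'   `run$config$expansion_year` if present.
#' @return A ggplot object.
#' @export
plot_trend <- function(run, fishery, variable, group, expansion_year = NULL) {
  expansion_year <- expansion_year %||% run$config$expansion_year
  ser <- run$series |>
    filter(.data$fishery == !!fishery, .data$variable == !!variable,
           .data$group == !!group)
  if (nrow(ser) == 0L) abort("No such series.")
  frow <- run$fits |>
    filter(.data$fishery == !!fishery, .data$variable == !!variable,
           .data$group == !!group)
  p <- ggplot2::ggplot(ser, ggplot2::aes(x = .data$year, y = .data$smoothed)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(title = sprintf("%s: %s (%s)", fishery, group, variable),
                  x = "Year", y = variable, size = "weight") +
    ggplot2::theme_minimal()
  if (nrow(frow) == 1L && isTRUE(frow$selected)) {
    fit <- frow$fit[[1L]]
    keep <- is.finite(ser$smoothed) & ser$weight > 0
    x_idx <- seq_len(nrow(ser))[keep]
    grid_x <- seq(min(x_idx), max(x_idx), length.out = 100)
    pr <- stats::predict(fit$model, newdata = data.frame(x = grid_x),
                         se.fit = TRUE)
    est <- pr$fit; lo <- pr$fit - 1.96 * pr$se.fit; hi <- pr$fit + 1.96 * pr$se.fit
    if (fit$form %in% c("exponential", "power")) {
      est <- exp(est); lo <- exp(lo); hi <- exp(hi)
    }
    band <- tibble(
      year = min(ser$year) + grid_x - 1, est = est, lo = lo, hi = hi
    )
    p <- p +
      ggplot2::geom_ribbon(data = band,
        ggplot2::aes(x = .data$year, ymin = .data$lo, ymax = .data$hi),
        inherit.aes = FALSE, alpha = 0.2) +
      ggplot2::geom_line(data = band,
        ggplot2::aes(x = .data$year, y = .data$est), inherit.aes = FALSE)
  }
  if (!is.null(expansion_year)) {
    p <- p + ggplot2::geom_vline(xintercept = expansion_year, linetype = "dashed")
  }
  p
}
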