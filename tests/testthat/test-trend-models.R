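test_that("moving average is centred with truncated endpoints", {
  expect_equal(moving_average(c(1, 2, 3, 4)), c(1.5, 2, 3, 3.5))
  expect_equal(moving_average(rep(7, 6)), rep(7, 6))
  expect_equal(moving_average(c(5, 1, 9, 2), window = 1), c(5, 1, 9, 2))
  expect_error(moving_average(numeric(0)), "empty")
  expect_error(moving_average(1:5, window = 2), "odd")
  # missing values are ignored within the window
  expect_equal(moving_average(c(1, NA, 3, 5))[2], 2)
})

test_that("noiseless linear data is recovered exactly with r2 = 1", {
  x <- 1:10
  y <- 2 * x + 1
  fits <- suppressWarnings(fit_candidates(y))  # perfect-fit chatter
  lin <- fits$linear
  expect_equal(unname(lin$coefficients$estimate), c(1, 2), tolerance = 1e-10)
  expect_equal(lin$r2, 1)
  expect_equal(lin$net_change, 2 * 9, tolerance = 1e-9)
})

test_that("equal weights reproduce unweighted least squares", {
  set.seed(12)
  y <- 5 + 0.4 * (1:12) + rnorm(12)
  f_w <- fit_candidates(y, weights = rep(7, 12))
  f_u <- stats::lm(y ~ x, data = data.frame(x = 1:12, y = y))
  expect_equal(f_w$linear$coefficients$estimate, unname(coef(f_u)),
               tolerance = 1e-10)
  f_q <- stats::lm(y ~ x + I(x^2), data = data.frame(x = 1:12, y = y))
  expect_equal(f_w$quadratic$coefficients$estimate, unname(coef(f_q)),
               tolerance = 1e-10)
})

test_that("log-response forms are skipped for non-positive data", {
  y <- c(-1, 2, 3, 4, 5, 6)
  expect_message(fits <- fit_candidates(y), "log-response")
  expect_setequal(names(fits), c("linear", "quadratic"))
})

test_that("inflating a point's weight pulls the fit toward it", {
  set.seed(3)
  y <- 10 + 0.5 * (1:10) + rnorm(10, sd = 2)
  res_at <- function(w_val) {
    w <- rep(1, 10); w[4] <- w_val
    f <- fit_candidates(y, weights = w)$linear
    abs(y[4] - unname(stats::fitted(f$model)[4]))
  }
  expect_lte(res_at(50), res_at(1))
  expect_lte(res_at(1000), res_at(50))
})

test_that("original-scale AIC ranks the generating form first for most replicates", {
  set.seed(61)
  hits <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    x <- 1:20
    y <- exp(1 + 0.15 * x + rnorm(20, sd = 0.2))
    fits <- fit_candidates(y)
    if (fits$exponential$aic < fits$linear$aic) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("model selection balances significance, normality and AIC", {
  stub <- function(p, shapiro, aic, dw = 2, form = "linear") {
    structure(list(form = form, p_value = p, shapiro_p = shapiro, aic = aic,
                   dw = dw, flags = character(), selected = FALSE),
              class = "creel_fit")
  }
  # only one significant fit -> it wins
  s <- select_model(list(linear = stub(0.01, 0.5, 10),
                         quadratic = stub(0.4, 0.5, -5)))
  expect_equal(s$form, "linear")
  # lower-AIC fit failing normality loses to a normal-residual fit
  s2 <- select_model(list(linear = stub(0.01, 0.5, 10),
                          quadratic = stub(0.01, 0.001, -5, form = "quadratic")))
  expect_equal(s2$form, "linear")
  expect_length(s2$flags, 0)
  # nothing significant -> no model
  expect_null(select_model(list(linear = stub(0.2, 0.5, 10))))
  # all significant fits violate normality -> flagged, min AIC
  s3 <- select_model(list(linear = stub(0.01, 0.001, 10),
                          quadratic = stub(0.01, 0.002, -5, form = "quadratic")))
  expect_equal(s3$form, "quadratic")
  expect_true("normality_violated" %in% s3$flags)
  # autocorrelation flags without vetoing
  s4 <- select_model(list(linear = stub(0.01, 0.5, 10, dw = 0.5)))
  expect_true("autocorrelated" %in% s4$flags)
  expect_error(select_model(list()), "Empty")
})

test_that("saturating data selects a log-family model most of the time", {
  set.seed(21)
  picks <- vapply(1:60, function(r) {
    x <- 1:20
    y <- exp(3 - 0.5 * log(x) + rnorm(20, sd = 0.1))
    best <- select_model(fit_candidates(y))
    if (is.null(best)) NA_character_ else best$form
  }, character(1))
  expect_gte(mean(picks %in% c("exponential", "power"), na.rm = TRUE), 0.8)
})

test_that("net change sign tracks the generating trend", {
  set.seed(5)
  ok <- vapply(1:100, function(r) {
    y <- 30 - 0.8 * (1:15) + rnorm(15, sd = 1.5)
    best <- select_model(fit_candidates(y))
    !is.null(best) && best$net_change < 0
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("equation strings mirror the compact published format", {
  x <- 1:10
  # suppress the perfect-fit chatter from summary.lm on noiseless input
  f <- suppressWarnings(fit_candidates(24.7 - 1.1 * x + 0.03 * x^2))$quadratic
  expect_equal(equation_string(f), "y = -1.1x + 0.03x^2 + 25")
  flin <- suppressWarnings(fit_candidates(2 * x + 1))$linear
  expect_equal(equation_string(flin), "y = 2x + 1")
})

test_that("tidy and glance methods expose coefficients and diagnostics", {
  set.seed(8)
  f <- fit_candidates(10 + 1:10 + rnorm(10, sd = 0.1))$linear
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("(Intercept)", "x"))
  gl <- glance(f)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("r.squared", "AIC", "shapiro_p", "dw", "net_change") %in%
                    names(gl)))
})

test_that("series with planted trends are built per fishery hierarchy", {
  scen <- demo_scenarios()
  rec <- simulate_catch(scen, effort_schedule(1985:2009, 1200, seed = 14), "bottom")
  attrs <- scenario_attributes(scen)
  cfg <- creel_config()
  filtered <- apply_filters(rec, attrs, cfg)
  cls <- classify_sizes(attrs |> dplyr::filter(species %in% filtered$species))
  ser <- build_series(filtered, cls, attrs, cfg)
  # dominant families only in the family series
  fam_tot <- filtered |>
    dplyr::group_by(family) |>
    dplyr::summarise(kg = sum(biomass_kg)) |>
    dplyr::mutate(share = 100 * kg / sum(kg))
  dom <- fam_tot$family[fam_tot$share > 10]
  expect_setequal(unique(ser$group[ser$variable == "family_contribution"]), dom)
  # percent contributions across all families sum to 100 per year (raw)
  all_fam <- filtered |>
    dplyr::group_by(year, family) |>
    dplyr::summarise(kg = sum(biomass_kg), .groups = "drop_last") |>
    dplyr::mutate(pct = 100 * kg / sum(kg)) |>
    dplyr::summarise(tot = sum(pct), .groups = "drop")
  expect_true(all(abs(all_fam$tot - 100) < 1e-9))
  # smoothed series keep raw length, weights non-negative
  expect_true(all(table(ser$variable, ser$group) %in% c(0, 25)))
  expect_true(all(ser$weight >= 0))
  # iconic series present (one scenario is iconic)
  expect_true("iconic_contribution" %in% ser$variable)
  # a fishery with one family at 100%: constant contribution series
  one <- mk_records("solo", "famX", rep(500, 30), year = rep(2001:2006, 5)) |>
    add_biomass(mk_attributes("solo", "famX"))
  ser1 <- build_series(one, NULL, NULL, cfg)
  fam1 <- ser1 |> dplyr::filter(variable == "family_contribution")
  expect_true(all(fam1$raw == 100))
})

test_that("the 70% cumulative rule picks the top species", {
  shares <- c(a = 40, b = 25, c = 10, d = 9, e = 8, f = 8)
  # emulate via one year-block of records whose biomass matches the shares
  rec <- purrr::imap_dfr(shares, function(s, nm) {
    mk_records(nm, "famA", rep(1000 * s / 10, 10),
               year = rep(2001:2010, length.out = 10))
  }) |> add_biomass(mk_attributes(names(shares), "famA"))
  cfg <- creel_config(min_n = 1, coverage_pct = 70)
  ser <- build_series(rec, NULL, NULL, cfg)
  sp <- unique(ser$group[ser$variable == "species_contribution"])
  expect_setequal(sp, c("a", "b", "c"))  # 40 + 25 + 10 = 75 >= 70
})

test_that("short series are flagged unfittable", {
  rec <- mk_records("s", "famA", rep(500, 9), year = rep(2001:2003, 3)) |>
    add_biomass(mk_attributes("s", "famA"))
  ser <- build_series(rec, NULL, NULL, creel_config(min_n = 1))
  expect_true(all(!ser$fittable))
  fits <- suppressWarnings(fit_trends(ser, creel_config()))
  expect_true(all(!fits$selected))
  expect_true(all(!fits$fittable))
})
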