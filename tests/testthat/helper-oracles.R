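# Exhaustive-search oracle for the natural-breaks optimum: enumerates every
# ordered partition of the sorted values into k contiguous classes and
# returns the minimal total within-class sum of squared deviations.
# Independent of the package's dynamic program.
brute_jenks_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- Inf
  for (cc in cuts) {
    bounds <- c(0, cc, n)
    tot <- 0
    for (i in seq_len(k)) {
      tot <- tot + ssd(x[(bounds[i] + 1):bounds[i + 1]])
    }
    best <- min(best, tot)
  }
  best
}

# Minimal species scenario with linear/constant/other trend paths.
mk_scenario <- function(id, fam, maxl, cstart, cnet, sstart, snet,
                        form_c = "linear", form_s = "linear",
                        cv = 0.12, iconic = FALSE, lw_a = 2e-8, lw_b = 3) {
  species_scenario(
    id, fam, maxl, lw_a, lw_b,
    contribution_path = trend_spec(form_c, cstart, cnet),
    size_path = trend_spec(form_s, sstart, snet),
    length_cv = cv, iconic = iconic
  )
}

# A small mixed-trend fishery used by several end-to-end tests.
demo_scenarios <- function() {
  list(
    mk_scenario("big_snapper", "snapper", 800, 0.20, -0.10, 520, -120,
                form_c = "exponential"),
    mk_scenario("small_snapper", "snapper", 350, 0.10, 0.10, 240, 0,
                form_s = "constant"),
    mk_scenario("mid_snapper", "snapper", 550, 0.08, 0, 380, -40),
    mk_scenario("big_grouper", "grouper", 900, 0.15, -0.08, 600, -80),
    mk_scenario("small_grouper", "grouper", 300, 0.08, 0.06, 220, 0,
                form_s = "constant"),
    mk_scenario("mid_grouper", "grouper", 500, 0.07, 0, 350, 0,
                form_c = "constant", form_s = "constant"),
    mk_scenario("big_emperor", "emperor", 600, 0.12, 0, 400, -60,
                form_c = "constant", form_s = "humped"),
    mk_scenario("small_emperor", "emperor", 300, 0.08, 0.02, 230, 0),
    mk_scenario("mid_emperor", "emperor", 450, 0.05, 0, 330, 0,
                form_c = "constant", form_s = "constant"),
    mk_scenario("goatfish_sp", "goatfish", 400, 0.05, 0, 280, -30,
                form_c = "constant"),
    mk_scenario("giant_jack", "jack", 1600, 0.02, 0.01, 900, 0,
                form_s = "constant", iconic = TRUE)
  )
}

# Hand-built catch records whose biomass is easy to reason about: with
# lw_b = 1 and lw_a = 1e-3 (mm -> kg), mass in kg equals fork length in m.
mk_records <- function(species, family, lengths_mm, year = 2000,
                       fishery = "bottom", sector = "north") {
  tibble::tibble(
    year = year, fishery = fishery, sector = sector,
    species = species, family = family,
    fork_length_mm = lengths_mm, count = 1L
  )
}

mk_attributes <- function(species, family, max_length_mm = 1e6,
                          lw_a = 1e-3, lw_b = 1, iconic = FALSE) {
  tibble::tibble(
    species = species, family = family, lw_a = lw_a, lw_b = lw_b,
    lw_source_tier = 1L, max_length_mm = max_length_mm, iconic = iconic
  )
}

# Stub of a selected model fit carrying just the fields the management
# classifier reads; independent of the regression code path.
mk_fit_stub <- function(form, net_change, deriv_first = sign(net_change),
                        effect = -0.5, effect_se = 0.05,
                        net_change_pct = 100 * net_change) {
  structure(list(
    form = form, net_change = net_change, deriv_first = deriv_first,
    effect = effect, effect_se = effect_se, net_change_pct = net_change_pct,
    coefficients = tibble::tibble(
      term = c("(Intercept)", "x"), estimate = c(1, effect),
      std.error = c(0.1, effect_se)
    ),
    r2 = 0.5, p_value = 0.001, aic = 0, shapiro_p = 0.5, dw = 2,
    n = 20L, selected = TRUE, flags = character()
  ), class = "creel_fit")
}
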