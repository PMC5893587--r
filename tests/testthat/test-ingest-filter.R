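# With lw_b = 1 and lw_a = 1e-3 the biomass of a record in kg equals its
# fork length in metres, so family/species shares can be set by hand.

test_that("families below 1% of overall biomass are dropped, at 1% kept", {
  attrs <- mk_attributes(c("a1", "b1"), c("famA", "famB"))
  rec <- dplyr::bind_rows(
    mk_records("a1", "famA", rep(1000, 199)),   # 199 kg
    mk_records("b1", "famB", 1000)              # 1 kg -> 0.5% of 200
  )
  out <- apply_filters(rec, attrs, creel_config(species_pct = 1e-9))
  expect_false("b1" %in% out$species)
  rep <- filter_report(out)
  expect_equal(rep$dropped_records$reason, "family<1%")
  expect_equal(rep$dropped_records$n, 1L)
  expect_equal(rep$dropped_families$family, "famB")

  # exactly 1.0% of the total: strict "<" keeps it
  rec2 <- dplyr::bind_rows(
    mk_records("a1", "famA", rep(1000, 99)),    # 99 kg
    mk_records("b1", "famB", 1000)              # 1 kg -> exactly 1%
  )
  out2 <- apply_filters(rec2, attrs, creel_config(species_pct = 1e-9))
  expect_true("b1" %in% out2$species)
  expect_equal(nrow(filter_report(out2)$dropped_records), 0L)
})

test_that("species below 1% of family biomass are dropped", {
  attrs <- mk_attributes(c("s1", "s2", "s3"), "famA")
  rec <- dplyr::bind_rows(
    mk_records("s1", "famA", rep(1000, 98)),  # 98 kg
    mk_records("s2", "famA", 1500),           # 1.5 kg
    mk_records("s3", "famA", 500)             # 0.5 kg
  )
  out <- apply_filters(rec, attrs, creel_config())
  expect_setequal(unique(out$species), c("s1", "s2"))
  rep <- filter_report(out)
  expect_equal(rep$dropped_species$species, "s3")
  expect_equal(rep$dropped_records$reason, "species<1%")
})

test_that("planted invalid measurements are dropped exactly", {
  set.seed(202)
  n <- 400
  lens <- round(runif(n, 200, 900))
  bad <- sample(n, n * 0.05)
  lens[bad] <- 0
  rec <- mk_records("s1", "famA", lens)
  attrs <- mk_attributes("s1", "famA", max_length_mm = 1000)
  out <- apply_filters(rec, attrs, creel_config())
  rep <- filter_report(out)
  expect_equal(nrow(out), n - length(bad))
  expect_equal(rep$dropped_records$reason, "invalid_measurement")
  expect_equal(rep$dropped_records$n, length(bad))

  # over-length records (beyond max_length x tolerance) are also errors
  rec2 <- mk_records("s1", "famA", c(500, 500, 1600))
  out2 <- apply_filters(rec2, attrs, creel_config(length_tolerance = 1.5))
  expect_equal(nrow(out2), 2L)
  expect_equal(filter_report(out2)$dropped_records$reason, "invalid_measurement")
})

test_that("location filter drops configured out-of-region sectors first", {
  rec <- dplyr::bind_rows(
    mk_records("s1", "famA", rep(500, 10), sector = "north"),
    mk_records("s1", "famA", rep(500, 4), sector = "offshore_bank")
  )
  attrs <- mk_attributes("s1", "famA")
  out <- apply_filters(rec, attrs,
                       creel_config(out_of_region_sectors = "offshore_bank"))
  expect_equal(nrow(out), 10L)
  expect_equal(filter_report(out)$dropped_records$reason, "out_of_region")
})

test_that("missing attributes error in strict mode, drop otherwise", {
  rec <- dplyr::bind_rows(mk_records("known", "famA", rep(500, 50)),
                          mk_records("mystery_fish", "famA", 500))
  attrs <- mk_attributes("known", "famA")
  expect_error(apply_filters(rec, attrs, creel_config(strict = TRUE)),
               "mystery_fish")
  out <- apply_filters(rec, attrs, creel_config(strict = FALSE))
  rep <- filter_report(out)
  expect_equal(rep$dropped_records$reason, "missing_attributes")
  expect_equal(nrow(out), 50L)
})

test_that("mass reconciles exactly and filtering is idempotent", {
  set.seed(99)
  scen <- demo_scenarios()
  rec <- simulate_catch(scen, effort_schedule(1990:2004, 400, seed = 8), "b")
  # plant some invalid lengths
  rec$fork_length_mm[sample(nrow(rec), 50)] <- 0
  attrs <- scenario_attributes(scen)
  out <- apply_filters(rec, attrs, creel_config())
  rep <- filter_report(out)
  expect_equal(rep$n_records_out + sum(rep$dropped_records$n), rep$n_records_in)
  expect_lt(abs(rep$mass_in_kg -
                  (rep$mass_out_kg + sum(rep$dropped_records$mass_kg))), 1e-9)
  # idempotence: a second pass drops nothing
  out2 <- apply_filters(out, attrs, creel_config())
  rep2 <- filter_report(out2)
  expect_equal(nrow(rep2$dropped_records), 0L)
  expect_equal(out2$biomass_kg, out$biomass_kg)
  expect_equal(nrow(out2), nrow(out))
})

test_that("every dropped item carries exactly one reason code", {
  rec <- dplyr::bind_rows(
    mk_records("s1", "famA", c(rep(1000, 99), 0), sector = "north"),  # 1 invalid
    mk_records("b1", "famB", 500, sector = "north"),                  # family<1%
    mk_records("s1", "famA", 500, sector = "far_away")                # location
  )
  attrs <- mk_attributes(c("s1", "b1"), c("famA", "famB"))
  out <- apply_filters(rec, attrs,
                       creel_config(out_of_region_sectors = "far_away",
                                    species_pct = 1e-9))
  rep <- filter_report(out)
  expect_setequal(rep$dropped_records$reason,
                  c("out_of_region", "invalid_measurement", "family<1%"))
  expect_equal(sum(rep$dropped_records$n), 3L)
  expect_false(any(duplicated(rep$dropped_records$reason)))
})

test_that("fishery timeframe follows the rolling-mean rule", {
  mk_kg <- function(kgs, years) {
    # one record per year whose biomass equals the wanted kg (lw_b = 1)
    tibble::tibble(year = years, fishery = "f1", sector = "n",
                   species = "s", family = "fam",
                   fork_length_mm = kgs * 1000, count = 1L,
                   biomass_kg = kgs)
  }
  # all rolling means below threshold -> empty range
  tf <- fishery_timeframe(mk_kg(c(10, 10, 10), 2001:2003), 50, 3)
  expect_equal(tf$n_years, 0L)
  expect_true(is.na(tf$start_year))
  # all above -> full range
  tf2 <- fishery_timeframe(mk_kg(rep(60, 4), 2001:2004), 50, 3)
  expect_equal(c(tf2$start_year, tf2$end_year), c(2001L, 2004L))
  # hand-computed example: means 45, 60, 83.3, 60, 33.3, 30, 30, 40
  tf3 <- fishery_timeframe(mk_kg(c(10, 80, 90, 80, 10, 10, 70, 10), 2001:2008),
                           50, 3)
  expect_equal(c(tf3$start_year, tf3$end_year, tf3$n_years), c(2002L, 2004L, 3L))
  expect_error(fishery_timeframe(mk_kg(rep(60, 4), 2001:2004), 50, 2), "odd")
})

test_that("attribute CSVs convert unit bases and keep the best tier", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    species = c("s1", "s1", "s2"), family = "famA",
    lw_a = c(0.01, 0.02, 0.015), lw_b = c(3, 3, 2.9),
    lw_source_tier = c(2L, 4L, 1L), max_length_mm = c(500, 500, 400),
    iconic = FALSE
  ), path)
  at <- read_attributes_csv(path, basis = "cm_g")
  expect_equal(nrow(at), 2L)
  expect_equal(at$lw_source_tier[at$species == "s1"], 2L)  # minimal tier wins
  # 300 mm fish, a=0.01 (cm/g), b=3: 0.01*30^3 g = 270 g = 0.27 kg
  expect_equal(to_biomass(300, at$lw_a[at$species == "s1"], 3), 0.27,
               tolerance = 1e-12)
})
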