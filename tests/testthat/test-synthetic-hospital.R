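test_that("default generator produces 81 units in 3 hospitals, deterministically", {
  hs <- generate_hospital(seed = 1)
  expect_length(hs$hospitals, 3L)
  units <- all_units(hs)
  expect_length(units, 81L)
  expect_true(all(vapply(hs$hospitals, function(h) length(h$units),
                         integer(1)) == 27L))
  # every unit in exactly one specialty group, groups of >= 2 units
  for (h in hs$hospitals) {
    ids <- vapply(h$units, `[[`, "", "unit_id")
    expect_setequal(unlist(h$specialty_groups), ids)
    expect_true(all(lengths(h$specialty_groups) >= 2L))
  }
  # byte-identical regeneration under the same seed
  expect_identical(hs, generate_hospital(seed = 1))
  expect_false(identical(hs, generate_hospital(seed = 2)))
})

test_that("unit profiles satisfy their invariants and reject bad inputs", {
  units <- all_units(generate_hospital(seed = 3))
  for (u in units[c(1, 40, 81)]) {
    expect_equal(sum(u$shift_weights), 1, tolerance = 1e-12)
    expect_gt(u$rn_skill_mix, 0)
    expect_lt(u$rn_skill_mix, 1)
    expect_gte(u$specialing_rate, 0)
  }
  expect_error(make_unit(beds = 0), class = "wardflex_config_error")
  expect_error(make_unit(shift_weights = c(0.5, 0.5, 0.5)),
               class = "wardflex_config_error")
  expect_error(make_unit(rn_skill_mix = 1), class = "wardflex_config_error")
  expect_error(generate_hospital(list(units_per_hospital = 0L)),
               class = "wardflex_config_error")
})

test_that("a one-unit specialty group generates with a vacuous-floating warning", {
  cfg <- small_gen_config(n_units = 1L, n_groups = 1L)
  expect_warning(hs <- generate_hospital(cfg, seed = 1), "floating is vacuous")
  expect_length(all_units(hs), 1L)
})

test_that("patient-mix draws respect census bounds and degenerate limits", {
  # beds 24, census distribution centred near the bed complement:
  # 10,000 draws never leave [0, beds], level counts always sum to census
  u <- make_unit(beds = 24, census_mean = 23, census_sd = 4,
                 specialing_rate = 0.5)
  draws <- wardflex:::with_seed(42, wardflex:::sample_patient_mix_n(u, 10000))
  expect_true(all(draws$census >= 0 & draws$census <= 24))
  expect_true(all(rowSums(draws$counts) == draws$census))
  expect_true(all(draws$specialing <= draws$census))

  # degenerate census at 0 forces an empty ward
  u0 <- make_unit(census_mean = 0, census_sd = 0)
  m0 <- sample_patient_mix(u0, day = 5, seed = 1)
  expect_identical(m0$census, 0L)
  expect_true(all(m0$level_counts == 0L))
  expect_identical(m0$specialing, 0L)

  # zero specialing rate never produces specialing demand
  uns <- wardflex:::with_seed(1, wardflex:::sample_patient_mix_n(make_unit(), 2000))
  expect_true(all(uns$specialing == 0L))

  # per-day determinism
  expect_identical(sample_patient_mix(u, 7, seed = 9),
                   sample_patient_mix(u, 7, seed = 9))
})

test_that("availability presets match their defining tables", {
  none <- availability_preset("none")
  expect_true(all(none$lookup == 0))
  higher <- availability_preset("higher")
  expect_true(all(higher$lookup == 0.5))
  unl <- availability_preset("unlimited")
  expect_true(all(unl$lookup["bank", , , ] == 0.5))
  expect_true(all(unl$lookup["agency", , , ] == 1.0))
  lim <- availability_preset("limited")
  expect_true(all(lim$lookup < 0.5))
  expect_true(all(lim$lookup >= 0))
  expect_equal(nrow(lim$table), 84L)
  expect_error(availability_preset("sometimes"),
               class = "wardflex_config_error")
  bad <- availability_preset("higher")$table
  bad$probability[1] <- 1.2
  expect_error(availability_scenario("x", bad),
               class = "wardflex_config_error")
})

test_that("shape statistics match an independent implementation and known cases", {
  skip_if_not_installed("e1071")
  x <- wardflex:::with_seed(11, rgamma(400, 4))
  expect_equal(sample_skewness(x), e1071::skewness(x, type = 2),
               tolerance = 1e-12)
  expect_equal(sample_excess_kurtosis(x), e1071::kurtosis(x, type = 2),
               tolerance = 1e-12)
  # symmetric two-point sample has zero skewness
  expect_equal(sample_skewness(rep(c(1, 2), 50)), 0)
  expect_true(is.na(sample_skewness(c(3, 3, 3))))
})

test_that("shape summary excludes degenerate units with a warning", {
  m <- rbind(a = c(1, 2, 3, 4, 6), b = rep(5, 5))
  expect_warning(s <- demand_shape_summary(m), "zero variance")
  expect_identical(s$excluded, "b")
  expect_identical(s$per_unit$unit_id, "a")
  m2 <- rbind(a = c(1, 2, 3, 4, 6), b = c(NA, NA, 2, NA, NA))
  expect_warning(s2 <- demand_shape_summary(m2), "fewer than 3")
})

test_that("default generator hits the demand-shape calibration targets", {
  # median per-unit skewness near 0.6 and median excess kurtosis near 0.7
  res <- sapply(1:3, function(s) {
    hs <- generate_hospital(seed = s)
    d <- demand_shape_summary(required_daily_hours(hs, 365, s))
    c(d$median_skewness, d$median_excess_kurtosis)
  })
  expect_equal(mean(res[1, ]), 0.6, tolerance = 0.2 / 0.6)
  expect_equal(mean(res[2, ]), 0.7, tolerance = 0.3 / 0.7)
})

test_that("mean census per unit-day is near the patient-day scale target", {
  hs <- generate_hospital(seed = 4)
  dem <- wardflex:::simulate_demand(hs, 1:120, 4, care_level_multipliers())
  # 677,809 patient days / 29,565 unit days = 22.9; require within 20%
  expect_equal(mean(dem$census), 22.9, tolerance = 0.2)
})

test_that("profiles and availability tables round-trip through CSV and JSON", {
  hs <- generate_hospital(small_gen_config(4L), seed = 6)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_unit_profiles(hs, csv)
  back <- read_unit_profiles(csv)
  expect_length(back, 4L)
  expect_equal(back[[2]]$census_dist$mean,
               all_units(hs)[[2]]$census_dist$mean)
  expect_equal(back[[3]]$acuity_mix_dist$base_mix,
               all_units(hs)[[3]]$acuity_mix_dist$base_mix)

  js <- withr::local_tempfile(fileext = ".json")
  write_hospital_json(hs, js)
  hs2 <- read_hospital_json(js)
  expect_equal(length(all_units(hs2)), 4L)
  # the round-tripped hospital drives identical demand draws
  expect_equal(required_daily_hours(hs2, 10, 1),
               required_daily_hours(hs, 10, 1))

  av <- availability_preset("limited")
  avcsv <- withr::local_tempfile(fileext = ".csv")
  write_availability(av, avcsv)
  expect_equal(read_availability(avcsv, "limited")$lookup, av$lookup)
})
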