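test_that("staffing costs follow rates, multipliers and patient days", {
  # 10 substantive RN hours at 20/h on a night shift with multiplier 1.3,
  # 2 patient days: total 260, 130 per patient day
  led <- data.frame(
    unit_id = "U1", day = 1L, shift = "night", role = "RN", census = 2L,
    required_hours = 10, rostered_hours = 10, absent_hours = 0,
    floated_out_hours = 0, floated_in_hours = 0, bank_hours = 0,
    agency_hours = 0, achieved_hours = 10, stringsAsFactors = FALSE
  )
  costs <- cost_parameters(hourly = rbind(RN = c(20, 18, 30),
                                          `NA` = c(15, 14, 20)),
                           unsocial = rbind(early = c(1, 1.45),
                                            late = c(1, 1.45),
                                            night = c(1.3, 1.45)))
  cs <- staffing_cost_summary(led, costs)
  expect_equal(cs$total_cost, 260)
  expect_equal(cs$cost_per_patient_day, 130)

  # sourcing the same hours from agency is strictly dearer
  led_a <- led
  led_a$rostered_hours <- 0
  led_a$agency_hours <- 10
  expect_gt(staffing_cost_summary(led_a, costs)$total_cost, 260)

  # zero hours cost nothing; zero patient days are an error
  led0 <- led
  led0[, c("rostered_hours", "achieved_hours")] <- 0
  expect_equal(staffing_cost_summary(led0, costs)$total_cost, 0)
  led0$census <- 0L
  expect_error(staffing_cost_summary(led0, costs),
               class = "wardflex_input_error")
})

test_that("reference levels are per-unit means of daily achieved HPPD", {
  led <- data.frame(
    unit_id = rep("U1", 2), day = 1:2, shift = "early", role = "RN",
    census = 10L, required_hours = 40, rostered_hours = 40,
    absent_hours = 0, floated_out_hours = 0, floated_in_hours = 0,
    bank_hours = 0, agency_hours = 0, achieved_hours = c(40, 60),
    stringsAsFactors = FALSE
  )
  # HPPD 4 then 6: reference 5
  expect_equal(unname(reference_levels(led)["U1"]), 5)
  expect_identical(reference_levels(led), reference_levels(led))
})

test_that("exposure thresholds are strict on both sides", {
  mk <- function(achieved, temp) data.frame(
    unit_id = "U1", day = seq_along(achieved), shift = "early", role = "RN",
    census = 10L, required_hours = 40, rostered_hours = achieved,
    absent_hours = 0, floated_out_hours = 0, floated_in_hours = 0,
    bank_hours = temp, agency_hours = 0, achieved_hours = achieved,
    stringsAsFactors = FALSE
  )
  eff <- effect_estimates(baseline_los_days = 5)
  # all unit-days exactly at the reference: zero low-staffing exposure
  led <- mk(c(40, 40, 40), c(0, 0, 0))
  ref <- reference_levels(led)
  e <- exposure_summary(led, ref, eff)
  expect_equal(e$prop_low_staffed, 0)
  # temporary HPPD exactly 1.5 is not flagged; 1.6 is
  led2 <- mk(c(40, 40), c(15, 16))
  e2 <- exposure_summary(led2, reference_levels(led2), eff)
  expect_equal(e2$prop_high_temporary, 0.5)
  # exposure days per admission = proportion x baseline length of stay
  expect_equal(e2$high_exposure_days, 0.5 * 5)
  expect_equal(e2$admissions, e2$patient_days / 5)
})

test_that("outcome effects follow the linear excess-risk form", {
  eff <- effect_estimates(rr_death_per_low_day = 1.03,
                          baseline_mortality_risk = 0.03)
  # 0.03 x 10000 x 0.03 x (-0.5) = -4.5 deaths
  oe <- outcome_effects(-0.5, 0, eff, admissions = 1e4)
  expect_equal(oe$delta_deaths, -4.5)
  # null effect and null exposure
  eff1 <- effect_estimates(rr_death_per_low_day = 1)
  expect_equal(outcome_effects(-2, 0, eff1, 1e4)$delta_deaths, 0)
  oe0 <- outcome_effects(0, 0, eff, 1e4)
  expect_equal(oe0$delta_deaths, 0)
  expect_equal(oe0$delta_bed_days, 0)
  # secondary variant adds the high-temporary term
  oe2 <- outcome_effects(-0.5, 0.2, eff, 1e4,
                         variant = "including_temporary_effects")
  expect_equal(oe2$delta_deaths,
               -4.5 + 0.03 * 1e4 * (eff$rr_death_high_temp - 1) * 0.2)
  # literal published expression, kept for audit
  lit <- outcome_effects(-0.5, 0, eff, 1e4, literal = TRUE)
  expect_equal(lit$delta_deaths, -0.5 * 1.03 * 0.03 * 1e4 - 0.03 * 1e4)
})

test_that("cost-effectiveness identities hold exactly", {
  ce <- cost_effectiveness(1e5, -10, 0, admissions = 1e4)
  expect_equal(ce$staff_cost_per_life, 1e4)
  expect_equal(ce$nn * ce$arr, 1, tolerance = 1e-15)
  expect_equal(ce$direction, "lives_saved")
  # bed-day offset reduces the net cost when stays shorten
  ce2 <- cost_effectiveness(1e5, -10, -100, 1e4,
                            cost_parameters(excess_bed_day_cost = 337))
  expect_equal(ce2$net_cost_per_life, (1e5 - 100 * 337) / 10)
  expect_lt(ce2$net_cost_per_life, ce2$staff_cost_per_life)
  # no-effect marker instead of a division blow-up
  ce0 <- cost_effectiveness(1e5, 0, 0, 1e4)
  expect_true(ce0$no_effect)
  expect_true(is.na(ce0$nn))
  expect_error(cost_effectiveness(1, -1, 0, 0),
               class = "wardflex_input_error")
})

test_that("shared-baseline NN identity reproduces the printed pair", {
  # NNT 665 at a -4.5% risk change implies NNH 361 at +8.3%
  expect_equal(round(implied_nn(665, -4.5, 8.3)), 361)
  # and the identity is its own inverse
  expect_equal(implied_nn(implied_nn(665, -4.5, 8.3), 8.3, -4.5), 665)
  expect_error(implied_nn(665, -4.5, 0), class = "wardflex_input_error")
})

test_that("comparisons of simulated plans have coherent signs", {
  hs <- generate_hospital(small_gen_config(8L), seed = 7)$hospitals[[1]]
  cfg <- simulator_config(days = 60, master_seed = 7,
                          availability = availability_preset("limited"))
  r_std <- run_scenario(hs, "standard", cfg)
  r_res <- run_scenario(hs, "resilient", cfg)
  cmp <- evaluate_comparison(r_res, r_std, r_std)
  # the higher-baseline plan costs more, reduces exposure, saves lives
  expect_gt(cmp$economics$delta_staff_cost, 0)
  expect_lte(cmp$delta_low_exposure_days, 0)
  expect_lte(cmp$economics$delta_deaths, 0)
  expect_lte(cmp$economics$delta_bed_days, 0)
  expect_lt(cmp$economics$net_cost_per_life, cmp$economics$staff_cost_per_life)
})

test_that("sensitivity grid honours its closed-form identities", {
  hs <- generate_hospital(small_gen_config(6L), seed = 8)$hospitals[[1]]
  cfg <- simulator_config(days = 40, master_seed = 8,
                          availability = availability_preset("limited"))
  r_std <- run_scenario(hs, "standard", cfg)
  r_res <- run_scenario(hs, "resilient", cfg)
  costs0 <- cost_parameters(excess_bed_day_cost = 0) # zero bed-day offset
  g <- sensitivity_grid(r_res, r_std, r_std, costs = costs0,
                        perturbations = c("identity", "all_costs_plus_25",
                                          "mortality_lower_ci",
                                          "agency_cost_plus_25"),
                        hospital = hs, config = cfg)
  base <- g$net_cost_per_life[g$perturbation == "identity"]
  # identity perturbation changes nothing (bit-for-bit recosting)
  expect_identical(g$change_vs_base[g$perturbation == "identity"], 0)
  # all costs +25% with zero bed-day offset scales net cost/life by 1.25
  expect_equal(g$net_cost_per_life[g$perturbation == "all_costs_plus_25"],
               1.25 * base, tolerance = 1e-12)
  # weaker mortality effect raises the cost per life saved
  expect_gt(g$change_vs_base[g$perturbation == "mortality_lower_ci"], 0)
  # agency perturbation is a no-op on a run with zero agency hours
  cfg_none <- simulator_config(days = 40, master_seed = 8,
                               availability = availability_preset("none"))
  rn_std <- run_scenario(hs, "standard", cfg_none)
  rn_res <- run_scenario(hs, "resilient", cfg_none)
  expect_equal(sum(rn_res$agency_hours) + sum(rn_std$agency_hours), 0)
  g2 <- sensitivity_grid(rn_res, rn_std, rn_std,
                         perturbations = c("identity",
                                           "agency_cost_plus_25"))
  expect_equal(g2$change_vs_base[g2$perturbation == "agency_cost_plus_25"],
               0)
  expect_error(sensitivity_grid(r_res, r_std, r_std,
                                perturbations = "discount_rate"),
               class = "wardflex_config_error")
})
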