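# Fixtures are built in code: no data files.

# a unit with fully controllable (possibly degenerate) distributions
make_unit <- function(id = "U01", group = "G1", beds = 24,
                      census_mean = 20, census_sd = 2,
                      base_mix = c(0.3, 0.25, 0.2, 0.15, 0.1),
                      shape = 40, tilt = 0, surge_prob = 0,
                      surge_factor = 1.8, specialing_rate = 0,
                      shift_weights = c(0.4, 0.35, 0.25),
                      rn_skill_mix = 0.5) {
  unit_profile(
    unit_id = id, specialty_group = group, beds = beds,
    census_dist = list(family = "discrete_truncnorm", mean = census_mean,
                       sd = census_sd),
    acuity_mix_dist = list(
      base_mix = stats::setNames(base_mix, c("0", "1a", "1b", "2", "3")),
      shape = shape, tilt = tilt, surge_prob = surge_prob,
      surge_factor = surge_factor
    ),
    specialing_rate = specialing_rate,
    shift_weights = shift_weights,
    rn_skill_mix = rn_skill_mix
  )
}

make_hospital <- function(units, id = "H1") {
  groups <- split(
    vapply(units, `[[`, "", "unit_id"),
    vapply(units, `[[`, "", "specialty_group")
  )
  structure(
    list(hospital_id = id, units = units, specialty_groups = groups),
    class = "hospital_profile"
  )
}

# small generator config for fast end-to-end runs
small_gen_config <- function(n_units = 6L, n_groups = 2L) {
  cfg <- default_gen_config()
  cfg$n_hospitals <- 1L
  cfg$units_per_hospital <- as.integer(n_units)
  cfg$groups_per_hospital <- as.integer(n_groups)
  cfg
}
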