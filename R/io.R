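# Plain-text round-trips for the package's data objects: unit profiles and
# hospitals, availability scenarios, establishment plans and shift ledgers.

unit_profile_row <- function(u) {
  data.frame(
    unit_id = u$unit_id, specialty_group = u$specialty_group, beds = u$beds,
    census_mean = u$census_dist$mean, census_sd = u$census_dist$sd,
    mix_0 = u$acuity_mix_dist$base_mix[[1]],
    mix_1a = u$acuity_mix_dist$base_mix[[2]],
    mix_1b = u$acuity_mix_dist$base_mix[[3]],
    mix_2 = u$acuity_mix_dist$base_mix[[4]],
    mix_3 = u$acuity_mix_dist$base_mix[[5]],
    acuity_shape = u$acuity_mix_dist$shape,
    acuity_tilt = u$acuity_mix_dist$tilt,
    surge_prob = u$acuity_mix_dist$surge_prob,
    surge_factor = u$acuity_mix_dist$surge_factor,
    specialing_rate = u$specialing_rate,
    w_early = u$shift_weights[[1]], w_late = u$shift_weights[[2]],
    w_night = u$shift_weights[[3]],
    rn_skill_mix = u$rn_skill_mix,
    stringsAsFactors = FALSE
  )
}

row_to_unit_profile <- function(r) {
  unit_profile(
    unit_id = r$unit_id, specialty_group = r$specialty_group, beds = r$beds,
    census_dist = list(family = "discrete_truncnorm", mean = r$census_mean,
                       sd = r$census_sd),
    acuity_mix_dist = list(
      base_mix = stats::setNames(
        c(r$mix_0, r$mix_1a, r$mix_1b, r$mix_2, r$mix_3), CARE_LEVELS),
      shape = r$acuity_shape, tilt = r$acuity_tilt,
      surge_prob = r$surge_prob, surge_factor = r$surge_factor
    ),
    specialing_rate = r$specialing_rate,
    shift_weights = c(r$w_early, r$w_late, r$w_night),
    rn_skill_mix = r$rn_skill_mix
  )
}

#' Write unit profiles to CSV (one row per unit)
#' @param x a `hospital_set`, `hospital_profile` or list of unit profiles.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_unit_profiles <- function(x, path) {
  units <- if (is.list(x) && !inherits(x, c("hospital_set",
                                            "hospital_profile"))) {
    x
  } else {
    all_units(x)
  }
  df <- do.call(rbind, lapply(units, unit_profile_row))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read unit profiles from CSV
#' @param path CSV written by [write_unit_profiles()].
#' @return A list of [unit_profile()] objects.
#' @export
read_unit_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) row_to_unit_profile(df[i, ]))
}

#' Serialise a hospital set to JSON
#' @param x a `hospital_set`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_hospital_json <- function(x, path) {
  obj <- list(
    seed = x$seed,
    gen_config = x$gen_config,
    hospitals = lapply(x$hospitals, function(h) {
      list(hospital_id = h$hospital_id,
           specialty_groups = h$specialty_groups,
           units = lapply(h$units, unclass))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a hospital set from JSON
#' @param path file written by [write_hospital_json()].
#' @return A `hospital_set`.
#' @export
read_hospital_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  hospitals <- lapply(obj$hospitals, function(h) {
    units <- lapply(h$units, function(u) {
      unit_profile(
        unit_id = u$unit_id, specialty_group = u$specialty_group,
        beds = u$beds,
        census_dist = u$census_dist,
        acuity_mix_dist = list(
          base_mix = stats::setNames(unlist(u$acuity_mix_dist$base_mix),
                                     CARE_LEVELS),
          shape = u$acuity_mix_dist$shape,
          tilt = u$acuity_mix_dist$tilt,
          surge_prob = u$acuity_mix_dist$surge_prob,
          surge_factor = u$acuity_mix_dist$surge_factor
        ),
        specialing_rate = u$specialing_rate,
        shift_weights = unlist(u$shift_weights),
        rn_skill_mix = u$rn_skill_mix,
        demand_shape = u$demand_shape
      )
    })
    structure(
      list(hospital_id = h$hospital_id, units = units,
           specialty_groups = lapply(h$specialty_groups, unlist)),
      class = "hospital_profile"
    )
  })
  structure(
    list(hospitals = hospitals, gen_config = obj$gen_config,
         seed = obj$seed),
    class = "hospital_set"
  )
}

#' Write an availability scenario to CSV
#' @param scenario an [availability_scenario()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_availability <- function(scenario, path) {
  utils::write.csv(scenario$table, path, row.names = FALSE)
  invisible(path)
}

#' Read an availability scenario from CSV
#' @param path CSV with columns source, role, shift, weekday, probability.
#' @param name scenario name.
#' @return An [availability_scenario()].
#' @export
read_availability <- function(path, name = "custom") {
  availability_scenario(name, utils::read.csv(path, stringsAsFactors = FALSE,
                                              na.strings = ""))
}

#' Write an establishment plan to CSV
#' @param plan an [build_establishment()] plan.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_establishment <- function(plan, path) {
  utils::write.csv(as.data.frame(plan), path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation ledger to CSV with a JSON run manifest
#' @param result a [run_scenario()] result.
#' @param path output CSV; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @return Invisibly, `path`.
#' @export
write_ledger <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  cfg <- attr(result, "config")
  manifest <- list(
    plan = attr(result, "plan"),
    availability = attr(result, "availability"),
    hospital_id = attr(result, "hospital_id"),
    master_seed = attr(result, "master_seed"),
    days = cfg$days,
    tolerance = cfg$tolerance,
    allow_floating = cfg$allow_floating,
    shift_length = cfg$shift_length
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
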