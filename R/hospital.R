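# Synthetic hospital generator.
#
# Emulates the statistical structure of a multi-hospital observational
# dataset of general medical/surgical inpatient units: per-unit census
# scale, acuity/dependency mix, 1:1 specialing demand, shift weighting,
# RN/assistant skill mix, and daily required-care-hours distributions with
# slight positive skew and positive excess kurtosis. No real unit-level
# data are used anywhere: every profile is drawn from parameterised
# distributions under a named seed.

#' Default generator configuration for the synthetic hospital set
#'
#' Returns the parameter set that defines the default study conditions:
#' 3 hospitals of 27 general medical/surgical units each (81 units total),
#' with census scale chosen so the mean daily census per unit is close to
#' 22.9 occupied beds, and an acuity-mix process tuned so the per-unit
#' distribution of required daily care hours shows a slight positive skew
#' (median near 0.6 across units, with roughly 16% of units above 1) and
#' positive excess kurtosis (median near 0.7).
#'
#' Daily required hours arise as census (truncated discrete normal) times
#' an acuity mix (tilted multinomial over the five care levels) times the
#' care-hour multipliers, plus 24 h per 1:1 specialing patient. A
#' gamma-distributed daily acuity factor with occasional symmetric (in log)
#' surge days supplies the right-skewing component; its shape parameter
#' varies across units (log-normal) to reproduce between-unit heterogeneity
#' in distribution shape.
#'
#' @return A named list of generator parameters.
#' @export
default_gen_config <- function() {
  list(
    n_hospitals = 3L,
    units_per_hospital = 27L,
    groups_per_hospital = 3L,
    beds_range = c(22L, 32L),
    occupancy_range = c(0.81, 0.91),
    census_cv = 0.10,
    base_acuity_mix = c("0" = 0.30, "1a" = 0.25, "1b" = 0.20,
                        "2" = 0.15, "3" = 0.10),
    acuity_mix_jitter_sd = 0.10,
    acuity_shape_median = 44,
    acuity_shape_log_sd = 1.5,
    acuity_tilt = 0.77,
    surge_prob = 0.045,
    surge_factor = 1.8,
    specialing_rate_range = c(0.1, 0.9),
    rn_skill_mix_range = c(0.44, 0.58),
    shift_weight_base = c(early = 0.40, late = 0.35, night = 0.25),
    shift_weight_jitter_sd = 0.02,
    target_skewness = 0.6,
    target_excess_kurtosis = 0.7
  )
}

SHIFTS <- c("early", "late", "night")
ROLES <- c("RN", "NA")
CARE_LEVELS <- c("0", "1a", "1b", "2", "3")

#' Construct a unit profile
#'
#' A `unit_profile` describes one ward: bed complement, specialty group
#' (the boundary within which staff may float), the distribution of daily
#' census, the acuity-mix process, the expected number of 1:1 specialing
#' patients per day, how daily staff hours are weighted across the three
#' shifts, and the RN share of required hours.
#'
#' @param unit_id opaque identifier.
#' @param specialty_group categorical label; floating never crosses it.
#' @param beds positive integer bed complement.
#' @param census_dist list with `mean` and `sd` of the (rounded, truncated
#'   to `[0, beds]`) normal daily census distribution.
#' @param acuity_mix_dist list with `base_mix` (probabilities over the five
#'   care levels, summing to 1), gamma `shape` of the daily acuity factor,
#'   `tilt` strength mapping the factor into the mix, and surge parameters
#'   `surge_prob`, `surge_factor`.
#' @param specialing_rate expected 1:1 patients per day (Poisson mean), >= 0.
#' @param shift_weights proportions over early/late/night summing to 1.
#' @param rn_skill_mix RN fraction of required core hours, in (0, 1).
#' @param demand_shape list of target shape statistics (informational).
#' @return An object of class `unit_profile`.
#' @export
unit_profile <- function(unit_id, specialty_group, beds, census_dist,
                         acuity_mix_dist, specialing_rate, shift_weights,
                         rn_skill_mix,
                         demand_shape = list(target_skewness = NA_real_,
                                             target_excess_kurtosis = NA_real_)) {
  beds <- as.integer(beds)
  if (is.na(beds) || beds <= 0L) stop_config("beds must be a positive integer")
  if (abs(sum(shift_weights) - 1) > 1e-9) {
    stop_config("shift_weights must sum to 1 (got ", sum(shift_weights), ")")
  }
  if (any(shift_weights < 0)) stop_config("shift_weights must be non-negative")
  if (length(shift_weights) != 3L) stop_config("shift_weights needs 3 entries")
  if (!(rn_skill_mix > 0 && rn_skill_mix < 1)) {
    stop_config("rn_skill_mix must lie strictly between 0 and 1")
  }
  if (specialing_rate < 0) stop_config("specialing_rate must be >= 0")
  mix <- acuity_mix_dist$base_mix
  if (length(mix) != 5L || abs(sum(mix) - 1) > 1e-6 || any(mix < 0)) {
    stop_config("acuity base_mix must be 5 non-negative probabilities summing to 1")
  }
  structure(
    list(
      unit_id = as.character(unit_id),
      specialty_group = as.character(specialty_group),
      beds = beds,
      census_dist = census_dist,
      acuity_mix_dist = acuity_mix_dist,
      specialing_rate = specialing_rate,
      shift_weights = stats::setNames(as.numeric(shift_weights), SHIFTS),
      rn_skill_mix = rn_skill_mix,
      demand_shape = demand_shape
    ),
    class = "unit_profile"
  )
}

#' @export
print.unit_profile <- function(x, ...) {
  cat("<unit_profile> ", x$unit_id, " (", x$specialty_group, "), ",
      x$beds, " beds, mean census ", round(x$census_dist$mean, 1),
      ", RN mix ", round(x$rn_skill_mix, 2), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic hospital set
#'
#' Draws a full set of hospitals and unit profiles from the generator
#' configuration. Deterministic given `(gen_config, seed)`. Under the
#' default configuration this produces 3 hospitals of 27 units each
#' (81 units in total), partitioned into specialty groups of 9 units.
#'
#' @param gen_config generator parameters, see [default_gen_config()].
#' @param seed integer master seed.
#' @return An object of class `hospital_set`: a list with element
#'   `hospitals`, each of class `hospital_profile` with fields
#'   `hospital_id`, `units` (list of [unit_profile()]) and
#'   `specialty_groups` (named list partitioning unit ids).
#' @export
#' @examples
#' hs <- generate_hospital(seed = 1)
#' length(all_units(hs)) # 81
generate_hospital <- function(gen_config = default_gen_config(), seed = 1L) {
  gc <- utils::modifyList(default_gen_config(), gen_config)
  if (gc$n_hospitals < 1L) stop_config("n_hospitals must be >= 1")
  if (gc$units_per_hospital < 1L) stop_config("units_per_hospital must be >= 1")
  if (any(gc$beds_range <= 0L)) stop_config("beds_range must be positive")
  if (gc$groups_per_hospital < 1L) stop_config("groups_per_hospital must be >= 1")

  hospitals <- with_seed(mix_seed(seed, .PURPOSE[["hospital"]]), {
    lapply(seq_len(gc$n_hospitals), function(h) {
      nu <- gc$units_per_hospital
      ng <- gc$groups_per_hospital
      group_of <- sort(rep_len(seq_len(ng), nu))
      units <- vector("list", nu)
      for (u in seq_len(nu)) {
        beds <- sample(seq(gc$beds_range[1], gc$beds_range[2]), 1L)
        occ <- stats::runif(1, gc$occupancy_range[1], gc$occupancy_range[2])
        mu_c <- beds * occ
        shape <- exp(stats::rnorm(1, log(gc$acuity_shape_median),
                                  gc$acuity_shape_log_sd))
        shape <- min(max(shape, 0.8), 80)
        mix <- gc$base_acuity_mix *
          exp(stats::rnorm(5, 0, gc$acuity_mix_jitter_sd))
        mix <- mix / sum(mix)
        sw <- gc$shift_weight_base +
          stats::rnorm(3, 0, gc$shift_weight_jitter_sd)
        sw <- pmax(sw, 0.05)
        sw <- sw / sum(sw)
        units[[u]] <- unit_profile(
          unit_id = sprintf("H%dU%02d", h, u),
          specialty_group = sprintf("H%dG%d", h, group_of[u]),
          beds = beds,
          census_dist = list(family = "discrete_truncnorm", mean = mu_c,
                             sd = gc$census_cv * mu_c),
          acuity_mix_dist = list(
            base_mix = stats::setNames(as.numeric(mix), CARE_LEVELS),
            shape = shape,
            tilt = gc$acuity_tilt,
            surge_prob = gc$surge_prob,
            surge_factor = gc$surge_factor
          ),
          specialing_rate = stats::runif(1, gc$specialing_rate_range[1],
                                         gc$specialing_rate_range[2]),
          shift_weights = sw,
          rn_skill_mix = stats::runif(1, gc$rn_skill_mix_range[1],
                                      gc$rn_skill_mix_range[2]),
          demand_shape = list(
            target_skewness = gc$target_skewness,
            target_excess_kurtosis = gc$target_excess_kurtosis
          )
        )
      }
      groups <- split(
        vapply(units, `[[`, "", "unit_id"),
        vapply(units, `[[`, "", "specialty_group")
      )
      small <- names(groups)[lengths(groups) < 2L]
      if (length(small)) {
        warning("specialty group(s) ", paste(small, collapse = ", "),
                " have fewer than 2 units: floating is vacuous there",
                call. = FALSE)
      }
      structure(
        list(hospital_id = sprintf("H%d", h), units = units,
             specialty_groups = groups),
        class = "hospital_profile"
      )
    })
  })
  structure(
    list(hospitals = hospitals, gen_config = gc, seed = as.integer(seed)),
    class = "hospital_set"
  )
}

#' @export
print.hospital_profile <- function(x, ...) {
  cat("<hospital_profile> ", x$hospital_id, ": ", length(x$units),
      " units in ", length(x$specialty_groups), " specialty groups\n",
      sep = "")
  invisible(x)
}

#' @export
print.hospital_set <- function(x, ...) {
  cat("<hospital_set> ", length(x$hospitals), " hospital(s), ",
      length(all_units(x)), " units total (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' All unit profiles of a hospital or hospital set
#' @param x a `hospital_set` or `hospital_profile`.
#' @return A flat list of `unit_profile` objects.
#' @export
all_units <- function(x) {
  if (inherits(x, "hospital_profile")) return(x$units)
  if (inherits(x, "hospital_set")) {
    return(unlist(lapply(x$hospitals, `[[`, "units"), recursive = FALSE))
  }
  if (inherits(x, "unit_profile")) return(list(x))
  stop_input("expected a hospital_set, hospital_profile or unit_profile")
}

# ---- patient-mix sampling ---------------------------------------------------

# z-scores of the care-level multipliers, used to tilt the acuity mix
level_zscores <- function(multipliers = care_level_multipliers()) {
  m <- multipliers$hours
  (m - mean(m)) / stats::sd(m)
}

# draw one day's patient mix with the current RNG stream (fixed call order)
draw_patient_mix_once <- function(unit, zlev) {
  cd <- unit$census_dist
  ad <- unit$acuity_mix_dist
  z <- stats::rnorm(1, cd$mean, cd$sd)
  census <- as.integer(min(unit$beds, max(0, round(z))))
  a <- stats::rgamma(1, shape = ad$shape, rate = ad$shape)
  u_surge <- stats::runif(1)
  u_dir <- stats::runif(1)
  if (u_surge < ad$surge_prob) {
    a <- a * if (u_dir < 0.5) 1 / ad$surge_factor else ad$surge_factor
  }
  w <- ad$base_mix * exp(ad$tilt * (a - 1) * zlev)
  p <- w / sum(w)
  counts <- integer(5L)
  rem <- census
  pleft <- 1
  for (l in 1:4) {
    pl <- min(max(p[l] / pleft, 0), 1)
    if (!is.finite(pl)) pl <- 0
    counts[l] <- stats::rbinom(1, rem, pl)
    rem <- rem - counts[l]
    pleft <- pleft - p[l]
  }
  counts[5L] <- rem
  specialing <- as.integer(min(stats::rpois(1, unit$specialing_rate), census))
  list(census = census, counts = counts, specialing = specialing, acuity = a)
}

# Draw the patient mixes of one unit for a vector of day indices. Each
# (unit, day) has its own sub-stream, so draws are identical no matter how
# many days are generated or in what order: the simulation engine, the
# establishment sampler and single-day accessors all see the same data.
sample_patient_mix_days <- function(unit, day_index, seed,
                                    purpose = .PURPOSE[["demand"]]) {
  n <- length(day_index)
  zlev <- level_zscores()
  uhash <- hash_id(unit$unit_id)
  census <- specialing <- integer(n)
  acuity <- numeric(n)
  counts <- matrix(0L, n, 5L, dimnames = list(NULL, CARE_LEVELS))
  # one save/restore of the caller's RNG state around the whole loop;
  # each unit-day still gets its own derived sub-seed
  had_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_old) assign(".Random.seed", old, envir = globalenv())
  })
  # derive the per-day seeds in one vectorised pass, identical to
  # mix_seed(seed, purpose, uhash, day)
  h0 <- ((104729 * 69069 + as.numeric(seed) %% 2147483647 + 1) %% 2147483647)
  h0 <- (h0 * 69069 + purpose %% 2147483647 + 1) %% 2147483647
  h0 <- (h0 * 69069 + as.numeric(uhash) %% 2147483647 + 1) %% 2147483647
  seeds <- (h0 * 69069 + as.numeric(day_index) %% 2147483647 + 1) %%
    2147483647
  for (j in seq_len(n)) {
    set.seed(seeds[j])
    d <- draw_patient_mix_once(unit, zlev)
    census[j] <- d$census
    counts[j, ] <- d$counts
    specialing[j] <- d$specialing
    acuity[j] <- d$acuity
  }
  list(census = census, counts = counts, specialing = specialing,
       acuity = acuity)
}

# n independent draws with the current RNG stream (distribution checks)
sample_patient_mix_n <- function(unit, n) {
  zlev <- level_zscores()
  census <- specialing <- integer(n)
  acuity <- numeric(n)
  counts <- matrix(0L, n, 5L, dimnames = list(NULL, CARE_LEVELS))
  for (j in seq_len(n)) {
    d <- draw_patient_mix_once(unit, zlev)
    census[j] <- d$census
    counts[j, ] <- d$counts
    specialing[j] <- d$specialing
    acuity[j] <- d$acuity
  }
  list(census = census, counts = counts, specialing = specialing,
       acuity = acuity)
}

#' Sample the patient mix of one unit on one day
#'
#' Returns the census, counts per care level and 1:1 specialing count for
#' `day`, drawn from the unit-day's demand sub-stream. Deterministic given
#' `(unit, day, seed)` and identical to the draw used by the simulation
#' engine under the same master seed.
#'
#' @param unit a [unit_profile()].
#' @param day positive integer day index.
#' @param seed integer master seed.
#' @return A list with `census`, `level_counts` (named integer vector over
#'   care levels, summing to `census`), `specialing` and `acuity`.
#' @export
sample_patient_mix <- function(unit, day, seed = 1L) {
  day <- as.integer(day)
  if (is.na(day) || day < 1L) stop_input("day must be a positive integer")
  draws <- sample_patient_mix_days(unit, day, seed)
  list(
    census = draws$census[1L],
    level_counts = stats::setNames(draws$counts[1L, ], CARE_LEVELS),
    specialing = draws$specialing[1L],
    acuity = draws$acuity[1L]
  )
}

# ---- availability scenarios -------------------------------------------------

#' Construct a temporary-staff availability scenario
#'
#' The fulfilment-probability table gives, for every combination of source
#' (bank, agency), role (RN, NA), shift (early, late, night) and weekday
#' (Mon..Sun), the probability that one requested half-shift block is
#' filled.
#'
#' @param name scenario name.
#' @param table data frame with columns `source`, `role`, `shift`,
#'   `weekday`, `probability` covering all 84 combinations.
#' @return An object of class `availability_scenario`.
#' @export
availability_scenario <- function(name, table) {
  need <- c("source", "role", "shift", "weekday", "probability")
  if (!all(need %in% names(table))) {
    stop_config("availability table needs columns ",
                paste(need, collapse = ", "))
  }
  if (any(table$probability < 0 | table$probability > 1)) {
    stop_config("fulfilment probabilities must lie in [0, 1]")
  }
  wd <- as.integer(table$weekday)
  if (any(is.na(wd)) || any(wd < 1L | wd > 7L)) {
    stop_config("weekday must be an integer in 1..7 (1 = Monday)")
  }
  lookup <- array(
    NA_real_, dim = c(2, 2, 3, 7),
    dimnames = list(c("bank", "agency"), ROLES, SHIFTS, NULL)
  )
  for (i in seq_len(nrow(table))) {
    lookup[table$source[i], table$role[i], table$shift[i], wd[i]] <-
      table$probability[i]
  }
  if (anyNA(lookup)) {
    stop_config("availability table must cover all source x role x shift x ",
                "weekday combinations")
  }
  structure(
    list(name = name, table = table, lookup = lookup),
    class = "availability_scenario"
  )
}

#' @export
print.availability_scenario <- function(x, ...) {
  cat("<availability_scenario> ", x$name, ": p in [",
      round(min(x$lookup), 2), ", ", round(max(x$lookup), 2), "]\n", sep = "")
  invisible(x)
}

#' Preset temporary-staff availability scenarios
#'
#' Four presets span the plausible range of short-notice temporary staff
#' supply: `"none"` (no bank or agency staff at all), `"limited"`
#' (empirical-style profile in which every fulfilment probability is below
#' 0.5 and varies by staff type, shift and weekday; shipped as a
#' synthetic, clearly-labelled emulation table), `"higher"` (every request
#' has a 50% chance of being filled from either source) and `"unlimited"`
#' (bank requests 50%, agency requests always filled).
#'
#' @param name one of `"none"`, `"limited"`, `"higher"`, `"unlimited"`.
#' @return An [availability_scenario()].
#' @export
#' @examples
#' availability_preset("none")$lookup[1, 1, 1, 1] # 0
availability_preset <- function(name = c("none", "limited", "higher",
                                         "unlimited")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("none", "limited", "higher", "unlimited")) {
    stop_config("unknown availability preset; presets are: ",
                "none, limited, higher, unlimited")
  }
  grid <- expand.grid(
    source = c("bank", "agency"), role = ROLES, shift = SHIFTS,
    weekday = 1:7, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  p <- switch(name,
    none = rep(0, nrow(grid)),
    higher = rep(0.5, nrow(grid)),
    unlimited = ifelse(grid$source == "agency", 1.0, 0.5),
    limited = NULL
  )
  if (name == "limited") {
    path <- system.file("extdata", "availability_limited_synthetic.csv",
                        package = "wardflex")
    if (!nzchar(path)) {
      stop_config("packaged limited-availability table not found")
    }
    tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
    return(availability_scenario("limited", tab))
  }
  grid$probability <- p
  availability_scenario(name, grid)
}

#' Fulfilment probability lookup
#' @param scenario an [availability_scenario()].
#' @param source `"bank"` or `"agency"`.
#' @param role `"RN"` or `"NA"`.
#' @param shift `"early"`, `"late"` or `"night"`.
#' @param weekday integer 1..7 (1 = Monday).
#' @return Probability in `[0, 1]`.
#' @export
p_fulfil <- function(scenario, source, role, shift, weekday) {
  scenario$lookup[source, role, shift, weekday]
}

# ---- distribution-shape summary ---------------------------------------------

#' Adjusted Fisher--Pearson sample skewness
#'
#' `G1 = g1 * sqrt(n (n-1)) / (n - 2)` with `g1 = m3 / m2^{3/2}`.
#'
#' @param x numeric vector.
#' @return Sample skewness, or `NA` if `n < 3` or the variance is zero.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(NA_real_)
  m3 <- mean((x - mean(x))^3)
  (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
}

#' Sample excess kurtosis (bias-adjusted, normal = 0)
#'
#' `G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3))` with `g2 = m4/m2^2 - 3`.
#'
#' @param x numeric vector.
#' @return Sample excess kurtosis, or `NA` if `n < 4` or zero variance.
#' @export
sample_excess_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4L) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(NA_real_)
  m4 <- mean((x - mean(x))^4)
  g2 <- m4 / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Distribution-shape summary of per-unit daily required hours
#'
#' Computes, for each unit, the adjusted Fisher--Pearson sample skewness
#' and the sample excess kurtosis of its daily required staffing hours,
#' plus cross-unit medians and the fraction of units with skewness above 1.
#' Units with fewer than 3 usable days or zero variance are excluded with a
#' warning.
#'
#' @param daily_hours numeric matrix, one row per unit (rownames are unit
#'   ids) and one column per day; see [required_daily_hours()].
#' @return A list of class `demand_shape_summary` with elements `per_unit`
#'   (data frame), `median_skewness`, `median_excess_kurtosis`,
#'   `prop_skewness_gt_1` and `excluded`.
#' @export
demand_shape_summary <- function(daily_hours) {
  if (is.data.frame(daily_hours)) daily_hours <- as.matrix(daily_hours)
  if (!is.matrix(daily_hours)) {
    stop_input("daily_hours must be a units x days matrix")
  }
  ids <- rownames(daily_hours) %||% sprintf("unit%03d", seq_len(nrow(daily_hours)))
  skew <- apply(daily_hours, 1, sample_skewness)
  kurt <- apply(daily_hours, 1, sample_excess_kurtosis)
  usable <- is.finite(skew) & is.finite(kurt)
  if (any(!usable)) {
    warning("excluding ", sum(!usable), " unit(s) with fewer than 3 ",
            "observations or zero variance: ",
            paste(ids[!usable], collapse = ", "), call. = FALSE)
  }
  per_unit <- data.frame(
    unit_id = ids[usable],
    n = rowSums(is.finite(daily_hours))[usable],
    skewness = skew[usable],
    excess_kurtosis = kurt[usable],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      per_unit = per_unit,
      median_skewness = stats::median(per_unit$skewness),
      median_excess_kurtosis = stats::median(per_unit$excess_kurtosis),
      prop_skewness_gt_1 = mean(per_unit$skewness > 1),
      excluded = ids[!usable]
    ),
    class = "demand_shape_summary"
  )
}

#' @export
print.demand_shape_summary <- function(x, ...) {
  cat("<demand_shape_summary> ", nrow(x$per_unit), " units: median skewness ",
      round(x$median_skewness, 3), ", median excess kurtosis ",
      round(x$median_excess_kurtosis, 3), ", ",
      round(100 * x$prop_skewness_gt_1), "% of units with skewness > 1\n",
      sep = "")
  invisible(x)
}
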