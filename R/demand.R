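# Demand model: patient mix -> required nursing hours per shift.
#
# Required hours follow the patient-classification logic of acuity-based
# staffing tools: each patient contributes the care hours of their care
# level, each 1:1 specialing patient adds a full day of care, and the
# daily total is split across shifts by the unit's shift weights and
# across roles by its RN skill mix.

#' Care-hours multipliers per care level
#'
#' Hours of nursing care required per patient per day at each of the five
#' acuity/dependency care levels, plus the hours added by one 1:1
#' specialing patient. The default multipliers are illustrative values on
#' the scale used by acuity-based staffing tools; they are configuration,
#' not estimates, and every report states the values used.
#'
#' @param hours named numeric vector of care hours per patient per day for
#'   levels `0, 1a, 1b, 2, 3`; must be positive and level 3 must not
#'   require fewer hours than level 0.
#' @param specialing_hours hours per 1:1 specialing patient per day.
#' @param specialing_role role that supplies specialing hours (`"NA"` by
#'   default; specialing is typically assistant work).
#' @return An object of class `care_level_multipliers`.
#' @export
care_level_multipliers <- function(hours = c("0" = 3, "1a" = 4.5, "1b" = 5.5,
                                             "2" = 9, "3" = 14),
                                   specialing_hours = 24,
                                   specialing_role = c("NA", "RN")) {
  specialing_role <- match.arg(specialing_role)
  if (length(hours) != 5L) stop_config("exactly 5 care-level multipliers needed")
  if (any(hours <= 0)) stop_config("care-level multipliers must be positive")
  if (hours[[5]] < hours[[1]]) {
    stop_config("level 3 multiplier must be >= level 0 multiplier")
  }
  if (specialing_hours <= 0) stop_config("specialing_hours must be positive")
  structure(
    list(hours = stats::setNames(as.numeric(hours), CARE_LEVELS),
         specialing_hours = specialing_hours,
         specialing_role = specialing_role),
    class = "care_level_multipliers"
  )
}

# core per-day demand arithmetic, vectorised over days
# counts: n x 5 matrix; specialing: length-n integer
# returns list with per-day totals and per-shift per-role matrices (n x 3)
required_hours_bulk <- function(counts, specialing, multipliers, rn_skill_mix,
                                shift_weights) {
  core <- drop(counts %*% multipliers$hours)
  spec <- specialing * multipliers$specialing_hours
  total <- core + spec
  if (multipliers$specialing_role == "NA") {
    rn_daily <- core * rn_skill_mix
  } else {
    rn_daily <- core * rn_skill_mix + spec
  }
  na_daily <- total - rn_daily
  list(
    total = total,
    rn = outer(rn_daily, shift_weights),
    na = outer(na_daily, shift_weights)
  )
}

#' Required care hours per shift for one patient mix
#'
#' Total daily required hours are the sum over care levels of (patient
#' count at the level times the level's multiplier), plus the specialing
#' count times `specialing_hours`. The daily total is split across shifts
#' by `shift_weights` and across roles by `rn_skill_mix` (specialing hours
#' go to the role configured in the multipliers).
#'
#' @param patient_mix list with `level_counts` (5 non-negative counts),
#'   `specialing` and `census`, as from [sample_patient_mix()].
#' @param multipliers a [care_level_multipliers()].
#' @param rn_skill_mix RN share of core hours, in (0, 1).
#' @param shift_weights proportions over early/late/night summing to 1.
#' @return A data frame with one row per shift: `shift`,
#'   `required_rn_hours`, `required_na_hours`, `census`.
#' @export
#' @examples
#' mix <- list(level_counts = c(10, 0, 0, 0, 0), specialing = 0, census = 10)
#' required_care_hours(mix, care_level_multipliers(), 0.5, c(0.4, 0.4, 0.2))
required_care_hours <- function(patient_mix, multipliers = care_level_multipliers(),
                                rn_skill_mix = 0.5,
                                shift_weights = c(0.4, 0.35, 0.25)) {
  counts <- as.numeric(patient_mix$level_counts)
  if (length(counts) != 5L) stop_input("level_counts must have 5 entries")
  if (any(counts < 0) || patient_mix$specialing < 0) {
    stop_input("patient counts must be non-negative")
  }
  if (abs(sum(shift_weights) - 1) > 1e-9) {
    stop_input("shift_weights must sum to 1")
  }
  b <- required_hours_bulk(matrix(counts, 1L), patient_mix$specialing,
                           multipliers, rn_skill_mix, shift_weights)
  data.frame(
    shift = SHIFTS,
    required_rn_hours = b$rn[1, ],
    required_na_hours = b$na[1, ],
    census = patient_mix$census %||% sum(counts),
    stringsAsFactors = FALSE
  )
}

# simulate demand for one hospital over a set of day indices: arrays over
# units x roles x shifts x positions (per-day draws shared by the day's
# three shifts; days independent)
simulate_demand <- function(hospital, day_index, seed, multipliers) {
  units <- all_units(hospital)
  n <- length(units)
  nd <- length(day_index)
  req <- array(0, dim = c(n, 2, 3, nd),
               dimnames = list(NULL, ROLES, SHIFTS, NULL))
  census <- matrix(0L, n, nd)
  total <- matrix(0, n, nd)
  for (i in seq_len(n)) {
    u <- units[[i]]
    draws <- sample_patient_mix_days(u, day_index, seed)
    b <- required_hours_bulk(draws$counts, draws$specialing, multipliers,
                             u$rn_skill_mix, u$shift_weights)
    req[i, "RN", , ] <- t(b$rn)
    req[i, "NA", , ] <- t(b$na)
    census[i, ] <- draws$census
    total[i, ] <- b$total
  }
  list(required = req, census = census, daily_total = total,
       day_index = day_index,
       unit_ids = vapply(units, `[[`, "", "unit_id"))
}

#' Per-unit daily required staffing hours
#'
#' Draws `days` independent daily demand realisations for every unit and
#' returns the daily total required hours (all roles, including
#' specialing) as a units x days matrix. This is the quantity whose
#' per-unit distribution shape is summarised by [demand_shape_summary()].
#'
#' @param hospital a `hospital_set` or `hospital_profile`.
#' @param days number of days to draw.
#' @param seed integer master seed.
#' @param multipliers a [care_level_multipliers()].
#' @return Numeric matrix with unit ids as rownames.
#' @export
required_daily_hours <- function(hospital, days = 365L, seed = 1L,
                                 multipliers = care_level_multipliers()) {
  dem <- simulate_demand(hospital, seq_len(days), seed, multipliers)
  rownames(dem$daily_total) <- dem$unit_ids
  dem$daily_total
}

#' Draw the demand realisation for one unit-shift
#'
#' Composes [sample_patient_mix()] and [required_care_hours()]: days are
#' independent draws (no serial correlation) and the three shifts of a day
#' share that day's patient mix, split by the unit's shift weights.
#'
#' @param unit a [unit_profile()].
#' @param day positive integer day index.
#' @param shift `"early"`, `"late"` or `"night"`.
#' @param seed integer master seed.
#' @param multipliers a [care_level_multipliers()].
#' @return One-row data frame: `unit_id`, `day`, `shift`,
#'   `required_rn_hours`, `required_na_hours`, `census`.
#' @export
draw_shift_demand <- function(unit, day, shift = SHIFTS, seed = 1L,
                              multipliers = care_level_multipliers()) {
  shift <- match.arg(shift)
  mix <- sample_patient_mix(unit, day, seed)
  r <- required_care_hours(mix, multipliers, unit$rn_skill_mix,
                           unit$shift_weights)
  out <- r[r$shift == shift, , drop = FALSE]
  cbind(data.frame(unit_id = unit$unit_id, day = as.integer(day),
                   stringsAsFactors = FALSE),
        out, row.names = NULL)
}

#' Establishment demand sample for one unit
#'
#' Draws the n-day sample of daily acuity/dependency-based demand used for
#' establishment setting (20 days by default, as recommended for
#' acuity-tool establishment reviews). Uses a sub-stream disjoint from the
#' simulation-period demand stream, so establishment sampling never
#' perturbs simulated days.
#'
#' @param unit a [unit_profile()].
#' @param n_days number of sampled days (default 20).
#' @param seed integer master seed.
#' @param multipliers a [care_level_multipliers()].
#' @return An object of class `demand_sample` with `daily_total_hours`,
#'   `daily_rn_hours`, `daily_na_hours` (length `n_days`) and per-shift
#'   matrices `rn_by_shift`, `na_by_shift`.
#' @export
establishment_sample <- function(unit, n_days = 20L, seed = 1L,
                                 multipliers = care_level_multipliers()) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop_input("n_days must be >= 1")
  draws <- sample_patient_mix_days(unit, seq_len(n_days), seed,
                                   purpose = .PURPOSE[["establishment"]])
  b <- required_hours_bulk(draws$counts, draws$specialing, multipliers,
                           unit$rn_skill_mix, unit$shift_weights)
  structure(
    list(
      unit_id = unit$unit_id,
      daily_total_hours = b$total,
      daily_rn_hours = rowSums(b$rn),
      daily_na_hours = rowSums(b$na),
      rn_by_shift = b$rn,
      na_by_shift = b$na
    ),
    class = "demand_sample"
  )
}

#' @export
print.demand_sample <- function(x, ...) {
  cat("<demand_sample> ", x$unit_id, ": ", length(x$daily_total_hours),
      " days, mean daily total ", round(mean(x$daily_total_hours), 1),
      " h\n", sep = "")
  invisible(x)
}

# analytic mean of a unit's daily required hours when the acuity process is
# degenerate (tilt 0, no surges): used as a closed-form check target
analytic_mean_daily_hours <- function(unit, multipliers = care_level_multipliers(),
                                      n_grid = 20000L) {
  cd <- unit$census_dist
  k <- 0:unit$beds
  if (cd$sd <= 0) {
    pc <- as.numeric(k == min(max(round(cd$mean), 0), unit$beds))
  } else {
    pc <- stats::pnorm(k + 0.5, cd$mean, cd$sd) -
      stats::pnorm(k - 0.5, cd$mean, cd$sd)
    pc[1] <- stats::pnorm(0.5, cd$mean, cd$sd)
    pc[length(pc)] <- 1 - stats::pnorm(unit$beds - 0.5, cd$mean, cd$sd)
    pc <- pc / sum(pc)
  }
  mean_census <- sum(k * pc)
  per_patient <- sum(unit$acuity_mix_dist$base_mix * multipliers$hours)
  # specialing truncated at census
  mean_spec <- sum(pc * vapply(k, function(cc) {
    s <- 0:cc
    ps <- stats::dpois(s, unit$specialing_rate)
    sum(s * ps) + cc * (1 - sum(ps))
  }, numeric(1)))
  mean_census * per_patient + mean_spec * multipliers$specialing_hours
}
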