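# Roster planner: establishment demand sample -> baseline rostered
# headcounts per unit x shift x role under the three staffing plans.

PLAN_KINDS <- c("flexible", "standard", "resilient")

# round to the nearest multiple of `granularity`, ties rounding up
round_headcount <- function(x, granularity = 0.5) {
  if (granularity <= 0) stop_config("granularity must be positive")
  floor(x / granularity + 0.5) * granularity
}

#' Baseline daily hours targeted by a staffing plan
#'
#' Applies the plan's target statistic to the establishment sample's daily
#' totals: `flexible` targets 80% of the sample mean, `standard` the
#' sample mean, and `resilient` the 90th percentile by the nearest-rank
#' method (the `ceiling(0.9 n)`-th order statistic). The statistic is
#' computed on daily totals; the RN/NA split is applied afterwards using
#' the sample's mean role shares.
#'
#' @param sample a [establishment_sample()] object, or a bare numeric
#'   vector of daily totals (in which case no role split is available).
#' @param plan_kind `"flexible"`, `"standard"` or `"resilient"`.
#' @return A list with `plan_kind`, `target_daily_hours`, `rn_hours`,
#'   `na_hours` and `rn_share`.
#' @export
#' @examples
#' plan_baseline_daily_hours(1:20, "resilient")$target_daily_hours # 18
plan_baseline_daily_hours <- function(sample, plan_kind = PLAN_KINDS) {
  plan_kind <- match.arg(plan_kind, PLAN_KINDS)
  if (inherits(sample, "demand_sample")) {
    totals <- sample$daily_total_hours
    rn_share <- if (sum(totals) > 0) {
      sum(sample$daily_rn_hours) / sum(totals)
    } else 0.5
  } else {
    totals <- as.numeric(sample)
    rn_share <- NA_real_
  }
  if (length(totals) == 0L) stop_input("establishment sample is empty")
  target <- switch(plan_kind,
    flexible = 0.8 * mean(totals),
    standard = mean(totals),
    resilient = sort(totals)[ceiling(0.9 * length(totals))]
  )
  list(
    plan_kind = plan_kind,
    target_daily_hours = target,
    rn_hours = target * rn_share,
    na_hours = target * (1 - rn_share),
    rn_share = rn_share
  )
}

#' Distribute daily baseline hours across shifts as rostered headcounts
#'
#' Per-shift hours are `daily_hours * weight`; the headcount is hours
#' divided by the shift length, rounded to the nearest half person (ties
#' round up), and the rostered hours are recomputed from the rounded
#' headcount, so every roster is deployable in whole and half shifts.
#'
#' @param daily_rn_hours,daily_na_hours baseline daily hours per role.
#' @param shift_weights proportions over early/late/night summing to 1.
#' @param shift_length shift length in hours (> 0).
#' @param granularity headcount rounding step (default 0.5 person).
#' @return Data frame with one row per shift x role: `shift`, `role`,
#'   `raw_hours`, `headcount`, `hours`.
#' @export
#' @examples
#' shift_roster(30, 0, c(0.4, 0.4, 0.2), shift_length = 8)
shift_roster <- function(daily_rn_hours, daily_na_hours,
                         shift_weights = c(0.4, 0.35, 0.25),
                         shift_length = 8, granularity = 0.5) {
  if (shift_length <= 0) stop_config("shift_length must be positive")
  if (daily_rn_hours < 0 || daily_na_hours < 0) {
    stop_input("daily hours must be non-negative")
  }
  raw <- c(outer(shift_weights, c(RN = daily_rn_hours, `NA` = daily_na_hours)))
  out <- data.frame(
    shift = rep(SHIFTS, 2L),
    role = rep(ROLES, each = 3L),
    raw_hours = raw,
    stringsAsFactors = FALSE
  )
  out$headcount <- round_headcount(out$raw_hours / shift_length, granularity)
  out$hours <- out$headcount * shift_length
  out
}

#' Whole-time-equivalent establishment implied by daily baseline hours
#'
#' Converts the daily worked hours at the bedside back into the number of
#' whole-time-equivalent staff to employ, re-adding the uplift for annual
#' leave, education and other time away from the unit:
#' `WTE = daily_hours * 7 / (weekly_hours * (1 - uplift_fraction))`.
#' Reporting only; the simulation operates on worked hours.
#'
#' @param daily_hours worked hours per day.
#' @param uplift_fraction fraction of employed time not worked at the
#'   bedside, in `[0, 1)`.
#' @param weekly_hours contracted hours per week per WTE.
#' @return WTE establishment (numeric).
#' @export
#' @examples
#' establishment_wte(75, uplift_fraction = 0.22) # 17.95
establishment_wte <- function(daily_hours, uplift_fraction = 0.22,
                              weekly_hours = 37.5) {
  if (uplift_fraction < 0 || uplift_fraction >= 1) {
    stop_config("uplift_fraction must lie in [0, 1)")
  }
  if (weekly_hours <= 0) stop_config("weekly_hours must be positive")
  daily_hours * 7 / (weekly_hours * (1 - uplift_fraction))
}

#' Build the establishment plan for a hospital
#'
#' For every unit: draw the 20-day establishment sample, apply the plan's
#' target statistic, and distribute the result across shifts and roles as
#' rostered headcounts. The establishment sample stream depends only on
#' `(seed, unit)`, so all plans built from the same seed are set against
#' identical demand samples.
#'
#' @param hospital a `hospital_profile` (or `hospital_set`; units are
#'   pooled).
#' @param plan_kind `"flexible"`, `"standard"` or `"resilient"`.
#' @param seed integer master seed.
#' @param shift_length shift length in hours.
#' @param granularity headcount rounding step.
#' @param multipliers a [care_level_multipliers()].
#' @param n_days establishment sample size.
#' @return A data frame of class `establishment_plan` with columns `plan`,
#'   `unit_id`, `shift`, `role`, `headcount`, `hours`; attribute
#'   `shift_length`.
#' @export
build_establishment <- function(hospital, plan_kind = PLAN_KINDS, seed = 1L,
                                shift_length = 8, granularity = 0.5,
                                multipliers = care_level_multipliers(),
                                n_days = 20L) {
  plan_kind <- match.arg(plan_kind, PLAN_KINDS)
  units <- all_units(hospital)
  rows <- lapply(units, function(u) {
    s <- establishment_sample(u, n_days, seed, multipliers)
    tgt <- plan_baseline_daily_hours(s, plan_kind)
    r <- shift_roster(tgt$rn_hours, tgt$na_hours, u$shift_weights,
                      shift_length, granularity)
    cbind(data.frame(plan = plan_kind, unit_id = u$unit_id,
                     stringsAsFactors = FALSE),
          r[, c("shift", "role", "headcount", "hours")], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "shift_length") <- shift_length
  attr(out, "granularity") <- granularity
  class(out) <- c("establishment_plan", "data.frame")
  out
}
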