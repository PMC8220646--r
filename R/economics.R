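# Health-economic evaluation: staffing costs, exposure to low staffing and
# to high temporary staffing, translation of exposure differences into
# deaths and bed days, NNT/NNH and incremental cost per life saved, and
# the parameter-perturbation sensitivity grid.

#' Staffing cost parameters
#'
#' Hourly employment costs by role and source, unsocial-hours pay
#' multipliers by shift and day type, and the reference cost of one
#' non-elective excess bed day (default 337, in GBP). The default hourly
#' rates are a single representative pay band per role with bank staff
#' slightly cheaper than substantive (reduced pension contributions) and
#' agency staff costed at a capped premium; all are configuration values
#' echoed in every report.
#'
#' @param hourly matrix of hourly costs, roles (RN, NA) x sources
#'   (substantive, bank, agency).
#' @param unsocial matrix of pay multipliers, shifts x day types
#'   (weekday, weekend); all entries must be >= 1.
#' @param excess_bed_day_cost cost of one excess bed day.
#' @param currency label used in reports.
#' @return An object of class `cost_parameters`.
#' @export
cost_parameters <- function(hourly = rbind(RN = c(27, 25.5, 28),
                                           `NA` = c(17, 16, 17.6)),
                            unsocial = rbind(early = c(1.00, 1.45),
                                             late = c(1.00, 1.45),
                                             night = c(1.30, 1.45)),
                            excess_bed_day_cost = 337,
                            currency = "GBP") {
  colnames(hourly) <- c("substantive", "bank", "agency")
  colnames(unsocial) <- c("weekday", "weekend")
  if (any(hourly < 0) || excess_bed_day_cost < 0) {
    stop_config("costs must be non-negative")
  }
  if (any(unsocial < 1)) stop_config("unsocial multipliers must be >= 1")
  structure(
    list(hourly = hourly, unsocial = unsocial,
         excess_bed_day_cost = excess_bed_day_cost, currency = currency),
    class = "cost_parameters"
  )
}

#' Effect estimates linking staffing exposure to outcomes
#'
#' Risk ratios per day of exposure and baseline outcome parameters used by
#' the economic model. The defaults are clearly-labelled illustrative
#' values on the scale reported by longitudinal studies of patient-level
#' exposure to low staffing; they are configuration, not estimates from
#' any specific dataset, and every report echoes the values used.
#'
#' @param rr_death_per_low_day risk ratio for death per day exposed to low
#'   staffing (with `rr_death_low_ci` lower/upper 95% bounds).
#' @param rr_death_low_ci length-2 numeric, 95% CI of the above.
#' @param los_pct_per_low_day percent change in length of stay per day of
#'   low-staffing exposure.
#' @param rr_death_high_temp risk ratio for death per day exposed to high
#'   temporary staffing.
#' @param high_temp_threshold temporary hours per patient day above which
#'   a unit-day counts as high-temporary (strict, default 1.5).
#' @param baseline_mortality_risk probability of death per admission.
#' @param baseline_los_days mean length of stay in days.
#' @return An object of class `effect_estimates`.
#' @export
effect_estimates <- function(rr_death_per_low_day = 1.03,
                             rr_death_low_ci = c(1.01, 1.05),
                             los_pct_per_low_day = 0.7,
                             rr_death_high_temp = 1.08,
                             high_temp_threshold = 1.5,
                             baseline_mortality_risk = 0.035,
                             baseline_los_days = 5) {
  if (rr_death_per_low_day <= 0 || rr_death_high_temp <= 0) {
    stop_input("risk ratios must be positive")
  }
  if (high_temp_threshold <= 0) stop_config("high_temp_threshold must be > 0")
  if (baseline_mortality_risk <= 0 || baseline_mortality_risk >= 1) {
    stop_config("baseline mortality risk must lie in (0, 1)")
  }
  if (baseline_los_days <= 0) stop_config("baseline_los_days must be > 0")
  structure(
    list(rr_death_per_low_day = rr_death_per_low_day,
         rr_death_low_ci = rr_death_low_ci,
         los_pct_per_low_day = los_pct_per_low_day,
         rr_death_high_temp = rr_death_high_temp,
         high_temp_threshold = high_temp_threshold,
         baseline_mortality_risk = baseline_mortality_risk,
         baseline_los_days = baseline_los_days),
    class = "effect_estimates"
  )
}

#' Total staffing cost and cost per patient day of a simulation run
#'
#' Costs rostered (substantive) hours at the substantive rate -- permanent
#' staff are salaried whether or not short-notice sickness occurs, and
#' floats redistribute rather than add hours -- plus bank and agency hours
#' at their rates, all scaled by the unsocial-hours multiplier of the
#' shift and day type. Cost per patient day divides by total patient days
#' (census summed once per unit-day).
#'
#' @param result a [run_scenario()] result.
#' @param costs a [cost_parameters()].
#' @return A list with `total_cost`, `patient_days`,
#'   `cost_per_patient_day` and a per-source breakdown `by_source`.
#' @export
staffing_cost_summary <- function(result, costs = cost_parameters()) {
  daytype <- ifelse(weekday_of(result$day) >= 6L, "weekend", "weekday")
  mult <- costs$unsocial[cbind(result$shift, daytype)]
  rate_sub <- costs$hourly[cbind(result$role, "substantive")]
  rate_bank <- costs$hourly[cbind(result$role, "bank")]
  rate_agency <- costs$hourly[cbind(result$role, "agency")]
  c_sub <- sum(result$rostered_hours * rate_sub * mult)
  c_bank <- sum(result$bank_hours * rate_bank * mult)
  c_agency <- sum(result$agency_hours * rate_agency * mult)
  key <- paste(result$unit_id, result$day, sep = "\r")
  pd <- sum(result$census[!duplicated(key)])
  if (pd <= 0) stop_input("no patient days: cost per patient day undefined")
  total <- c_sub + c_bank + c_agency
  list(total_cost = total, patient_days = pd,
       cost_per_patient_day = total / pd,
       by_source = c(substantive = c_sub, bank = c_bank, agency = c_agency))
}

#' Per-unit reference staffing levels from a standard-plan run
#'
#' The unit mean of daily achieved hours per patient day over unit-days
#' with non-zero census, computed from the standard-plan run; low staffing
#' on any plan is judged against these unit means.
#'
#' @param standard_result a [run_scenario()] result under the standard plan.
#' @return Named numeric vector of mean achieved HPPD per unit.
#' @export
reference_levels <- function(standard_result) {
  ud <- unit_day_summary(standard_result)
  ok <- ud[!is.na(ud$achieved_hppd), ]
  dropped <- setdiff(unique(ud$unit_id), unique(ok$unit_id))
  if (length(dropped)) {
    warning("unit(s) with no non-zero-census days excluded from reference: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  tapply(ok$achieved_hppd, ok$unit_id, mean)
}

#' Exposure to low staffing and high temporary staffing
#'
#' A unit-day is low-staffed iff its achieved HPPD is strictly below the
#' unit's reference mean, and high-temporary iff its bank-plus-agency
#' hours per patient day strictly exceed the threshold. Exposure
#' proportions are weighted by patient days, and converted to mean
#' exposure days per admission via the baseline length of stay.
#'
#' @param result a [run_scenario()] result.
#' @param reference per-unit reference HPPD from [reference_levels()].
#' @param effects an [effect_estimates()] (supplies the high-temporary
#'   threshold and baseline length of stay).
#' @return A list of class `exposure_summary` with elements
#'   `prop_low_staffed`, `prop_high_temporary`, `low_exposure_days`,
#'   `high_exposure_days` (per admission), `patient_days`, `admissions`.
#' @export
exposure_summary <- function(result, reference,
                             effects = effect_estimates()) {
  ud <- unit_day_summary(result)
  if (!all(unique(ud$unit_id) %in% names(reference))) {
    stop_input("reference levels missing for some units")
  }
  ok <- ud[ud$census > 0, ]
  low <- ok$achieved_hppd < reference[ok$unit_id]
  high <- ok$temporary_hppd > effects$high_temp_threshold
  pd <- sum(ok$census)
  prop_low <- sum(ok$census[low]) / pd
  prop_high <- sum(ok$census[high]) / pd
  structure(
    list(prop_low_staffed = prop_low,
         prop_high_temporary = prop_high,
         low_exposure_days = prop_low * effects$baseline_los_days,
         high_exposure_days = prop_high * effects$baseline_los_days,
         patient_days = pd,
         admissions = pd / effects$baseline_los_days),
    class = "exposure_summary"
  )
}

#' Translate exposure differences into deaths and bed days
#'
#' Default form: the change in deaths is the linear excess-risk expression
#' `baseline_risk * admissions * (rr - 1) * delta_exposure_days`, summed
#' over low-staffing exposure and (in the secondary-analysis variant)
#' high-temporary-staffing exposure. The change in bed days is
#' `admissions * baseline_los * (los_pct / 100) * delta_low_days`. A
#' literal-formula mode evaluates the compact published expression
#' `(delta_exposure * RR * baseline_risk * population) - baseline deaths`
#' verbatim for audit; it is not used by the default pipeline.
#'
#' @param delta_low_days change in low-staffing exposure days per
#'   admission (scenario minus reference).
#' @param delta_high_days change in high-temporary exposure days per
#'   admission.
#' @param effects an [effect_estimates()].
#' @param admissions admissions in the population.
#' @param variant `"low_staffing_only"` (primary) or
#'   `"including_temporary_effects"` (secondary).
#' @param literal if `TRUE`, use the literal published expression.
#' @return A list with `delta_deaths` and `delta_bed_days`.
#' @export
#' @examples
#' outcome_effects(-0.5, 0, effect_estimates(baseline_mortality_risk = 0.03,
#'   rr_death_per_low_day = 1.03), admissions = 1e4)$delta_deaths # -4.5
outcome_effects <- function(delta_low_days, delta_high_days = 0,
                            effects = effect_estimates(),
                            admissions,
                            variant = c("low_staffing_only",
                                        "including_temporary_effects"),
                            literal = FALSE) {
  variant <- match.arg(variant)
  if (effects$rr_death_per_low_day <= 0) stop_input("risk ratio must be > 0")
  base_deaths <- effects$baseline_mortality_risk * admissions
  if (literal) {
    dd <- delta_low_days * effects$rr_death_per_low_day *
      effects$baseline_mortality_risk * admissions - base_deaths
  } else {
    dd <- base_deaths * (effects$rr_death_per_low_day - 1) * delta_low_days
    if (variant == "including_temporary_effects") {
      dd <- dd + base_deaths * (effects$rr_death_high_temp - 1) * delta_high_days
    }
  }
  dbd <- admissions * effects$baseline_los_days *
    (effects$los_pct_per_low_day / 100) * delta_low_days
  list(delta_deaths = dd, delta_bed_days = dbd)
}

#' Cost-effectiveness of a plan comparison
#'
#' Computes the absolute risk reduction (or increase) per admission, the
#' number needed to treat `NNT = 1/ARR` (or harm, `NNH = 1/ARI`), and the
#' staff and net cost per life saved. Deltas are scenario minus reference;
#' a negative `delta_deaths` means lives saved, and the bed-day offset
#' `delta_bed_days * excess_bed_day_cost` (negative when stays shorten)
#' is added to the staff-cost delta to give the net cost. When
#' `delta_deaths` is zero the comparison is returned as an explicit
#' no-effect result with `NA` ratios rather than a division blow-up.
#'
#' @param delta_staff_cost staff-cost difference (scenario - reference).
#' @param delta_deaths change in deaths (negative = lives saved).
#' @param delta_bed_days change in bed days.
#' @param admissions admissions in the population (> 0).
#' @param costs a [cost_parameters()] (for the excess-bed-day cost).
#' @return A list of class `economic_result`.
#' @export
#' @examples
#' cost_effectiveness(1e5, -10, 0, 1e4)$staff_cost_per_life # 10000
cost_effectiveness <- function(delta_staff_cost, delta_deaths,
                               delta_bed_days = 0, admissions,
                               costs = cost_parameters()) {
  if (admissions <= 0) stop_input("admissions must be positive")
  no_effect <- delta_deaths == 0
  arr <- abs(delta_deaths) / admissions
  lives <- abs(delta_deaths)
  net <- delta_staff_cost + delta_bed_days * costs$excess_bed_day_cost
  structure(
    list(
      delta_staff_cost = delta_staff_cost,
      delta_deaths = delta_deaths,
      delta_bed_days = delta_bed_days,
      bed_day_offset = delta_bed_days * costs$excess_bed_day_cost,
      admissions = admissions,
      no_effect = no_effect,
      direction = if (no_effect) "none" else
        if (delta_deaths < 0) "lives_saved" else "lives_lost",
      arr = if (no_effect) NA_real_ else arr,
      nn = if (no_effect) NA_real_ else 1 / arr,
      staff_cost_per_life = if (no_effect) NA_real_ else
        delta_staff_cost / lives,
      net_cost_per_life = if (no_effect) NA_real_ else net / lives
    ),
    class = "economic_result"
  )
}

#' @export
print.economic_result <- function(x, ...) {
  if (x$no_effect) {
    cat("<economic_result> no effect on deaths; cost ratios undefined\n")
    return(invisible(x))
  }
  lab <- if (x$direction == "lives_saved") "NNT" else "NNH"
  cat("<economic_result> delta deaths ", round(x$delta_deaths, 2), ", ",
      lab, " ", round(x$nn), ", staff cost/life ",
      round(x$staff_cost_per_life), ", net cost/life ",
      round(x$net_cost_per_life), "\n", sep = "")
  invisible(x)
}

#' Implied number needed to harm/treat under a shared baseline
#'
#' Two comparisons sharing a baseline risk satisfy
#' `NN_B = NN_A * |deltaRR_A| / |deltaRR_B|`, because each NN is the
#' reciprocal of `baseline_risk * |deltaRR|`. This converts a known NNT at
#' one relative-risk change into the NN implied at another.
#'
#' @param nn_a number needed to treat/harm of comparison A.
#' @param delta_rr_a,delta_rr_b relative-risk changes (e.g. -0.045 or
#'   -4.5 for -4.5%; only magnitudes matter, units must agree).
#' @return The implied NN of comparison B (unrounded).
#' @export
#' @examples
#' round(implied_nn(665, -4.5, 8.3)) # 361
implied_nn <- function(nn_a, delta_rr_a, delta_rr_b) {
  if (delta_rr_b == 0) stop_input("delta_rr_b must be non-zero")
  nn_a * abs(delta_rr_a) / abs(delta_rr_b)
}

#' Evaluate one plan comparison end to end
#'
#' Runs the full economics pipeline for `result_new` vs `result_base`:
#' staffing costs, reference levels from the standard-plan run, exposure
#' summaries, outcome effects and cost-effectiveness.
#'
#' @param result_new,result_base simulation results for the compared plans.
#' @param result_standard the standard-plan run used for reference levels
#'   (defaults to `result_base`).
#' @param costs a [cost_parameters()].
#' @param effects an [effect_estimates()].
#' @param variant analysis variant, see [outcome_effects()].
#' @return A list of class `plan_comparison` containing the
#'   [cost_effectiveness()] result plus exposure and percentage deltas.
#' @export
evaluate_comparison <- function(result_new, result_base,
                                result_standard = result_base,
                                costs = cost_parameters(),
                                effects = effect_estimates(),
                                variant = c("low_staffing_only",
                                            "including_temporary_effects")) {
  variant <- match.arg(variant)
  ref <- reference_levels(result_standard)
  cost_new <- staffing_cost_summary(result_new, costs)
  cost_base <- staffing_cost_summary(result_base, costs)
  exp_new <- exposure_summary(result_new, ref, effects)
  exp_base <- exposure_summary(result_base, ref, effects)
  admissions <- exp_base$admissions
  d_low <- exp_new$low_exposure_days - exp_base$low_exposure_days
  d_high <- exp_new$high_exposure_days - exp_base$high_exposure_days
  oe <- outcome_effects(d_low, d_high, effects, admissions, variant)
  ce <- cost_effectiveness(cost_new$total_cost - cost_base$total_cost,
                           oe$delta_deaths, oe$delta_bed_days,
                           admissions, costs)
  base_deaths <- effects$baseline_mortality_risk * admissions
  base_bed_days <- admissions * effects$baseline_los_days
  structure(
    list(
      variant = variant,
      plan_new = attr(result_new, "plan"),
      plan_base = attr(result_base, "plan"),
      availability = attr(result_new, "availability"),
      delta_low_exposure_days = d_low,
      delta_high_exposure_days = d_high,
      staff_cost_pct = 100 * (cost_new$total_cost / cost_base$total_cost - 1),
      bed_days_pct = 100 * oe$delta_bed_days / base_bed_days,
      deaths_pct = 100 * oe$delta_deaths / base_deaths,
      cost_new = cost_new, cost_base = cost_base,
      exposure_new = exp_new, exposure_base = exp_base,
      economics = ce
    ),
    class = "plan_comparison"
  )
}

#' Sensitivity grid: change in net cost per life saved
#'
#' Re-evaluates one plan comparison under named parameter perturbations
#' and reports each perturbation's net cost per life saved minus the base
#' case's. All perturbations except `no_floating` are recostings or
#' re-evaluations of the stored simulation results; `no_floating`
#' re-simulates both plans with floating disabled (recomputing the
#' reference levels from its own standard run).
#'
#' Available perturbations: `identity`, `mortality_upper_ci`,
#' `mortality_lower_ci`, `bed_day_cost_plus_25`, `agency_cost_plus_25`,
#' `agency_equals_bank`, `bank_equals_substantive`, `no_floating`,
#' `all_costs_plus_25`.
#'
#' @param result_new,result_base,result_standard as in
#'   [evaluate_comparison()].
#' @param costs,effects base parameters.
#' @param variant analysis variant.
#' @param perturbations character vector of perturbation names.
#' @param hospital,config required only when `no_floating` is requested:
#'   the hospital profile and the [simulator_config()] used for the base
#'   runs.
#' @return A data frame with one row per perturbation: `perturbation`,
#'   `net_cost_per_life`, `change_vs_base`.
#' @export
sensitivity_grid <- function(result_new, result_base,
                             result_standard = result_base,
                             costs = cost_parameters(),
                             effects = effect_estimates(),
                             variant = "low_staffing_only",
                             perturbations = c("identity",
                                               "mortality_upper_ci",
                                               "mortality_lower_ci",
                                               "bed_day_cost_plus_25",
                                               "agency_cost_plus_25",
                                               "agency_equals_bank",
                                               "bank_equals_substantive",
                                               "all_costs_plus_25"),
                             hospital = NULL, config = NULL) {
  known <- c("identity", "mortality_upper_ci", "mortality_lower_ci",
             "bed_day_cost_plus_25", "agency_cost_plus_25",
             "agency_equals_bank", "bank_equals_substantive",
             "no_floating", "all_costs_plus_25")
  bad <- setdiff(perturbations, known)
  if (length(bad)) {
    stop_config("unknown perturbation(s): ", paste(bad, collapse = ", "),
                "; known: ", paste(known, collapse = ", "))
  }
  base <- evaluate_comparison(result_new, result_base, result_standard,
                              costs, effects, variant)
  base_net <- base$economics$net_cost_per_life
  one <- function(p) {
    cs <- costs; ef <- effects
    rn <- result_new; rb <- result_base; rs <- result_standard
    if (p == "mortality_upper_ci") {
      ef$rr_death_per_low_day <- ef$rr_death_low_ci[2]
    } else if (p == "mortality_lower_ci") {
      ef$rr_death_per_low_day <- ef$rr_death_low_ci[1]
    } else if (p == "bed_day_cost_plus_25") {
      cs$excess_bed_day_cost <- cs$excess_bed_day_cost * 1.25
    } else if (p == "agency_cost_plus_25") {
      cs$hourly[, "agency"] <- cs$hourly[, "agency"] * 1.25
    } else if (p == "agency_equals_bank") {
      cs$hourly[, "agency"] <- cs$hourly[, "bank"]
    } else if (p == "bank_equals_substantive") {
      cs$hourly[, "bank"] <- cs$hourly[, "substantive"]
    } else if (p == "all_costs_plus_25") {
      cs$hourly <- cs$hourly * 1.25
      cs$excess_bed_day_cost <- cs$excess_bed_day_cost * 1.25
    } else if (p == "no_floating") {
      if (is.null(hospital) || is.null(config)) {
        stop_config("no_floating perturbation needs `hospital` and `config`")
      }
      cfg <- config
      cfg$allow_floating <- FALSE
      rb <- run_scenario(hospital, attr(result_base, "plan"), cfg)
      rn <- run_scenario(hospital, attr(result_new, "plan"), cfg)
      rs <- if (attr(result_standard, "plan") == attr(result_base, "plan")) {
        rb
      } else {
        run_scenario(hospital, attr(result_standard, "plan"), cfg)
      }
    }
    evaluate_comparison(rn, rb, rs, cs, ef, variant)$economics$net_cost_per_life
  }
  net <- vapply(perturbations, one, numeric(1))
  data.frame(
    perturbation = perturbations,
    net_cost_per_life = unname(net),
    change_vs_base = unname(net - base_net),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
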