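# Shift engine: absence draws, shortfall classification against the 15%
# tolerance, floating within specialty groups, bank and agency hires under
# an availability scenario, and the achieved-staffing ledger.
#
# All deployments move in half-shift blocks: a block is half a shift worked
# by one person (shift_length / 2 hours), matching the constraint that
# whole people are deployed for a half or whole shift.

#' Simulator configuration
#'
#' @param tolerance shortfall fraction that triggers fill attempts
#'   (default 0.15, the tolerance used by workload-based staffing tools).
#' @param absence_rates per-shift short-notice sickness probability per
#'   half-person slot, by role (defaults: RN 0.03, NA 0.04).
#' @param allow_floating whether staff may float between units of a
#'   specialty group.
#' @param availability an [availability_scenario()].
#' @param days simulated days (default 365, one model run).
#' @param shift_length shift length in hours.
#' @param deployment_granularity `"half"` (half-shift blocks) or `"full"`.
#' @param master_seed integer seed; scenarios sharing it share demand and
#'   absence streams (common random numbers).
#' @param multipliers a [care_level_multipliers()].
#' @param max_headcount largest rostered headcount per unit-shift-role the
#'   engine reserves absence slots for.
#' @param max_blocks largest number of temporary-staff blocks requestable
#'   per unit-shift-role.
#' @return A list of class `simulator_config`.
#' @export
simulator_config <- function(tolerance = 0.15,
                             absence_rates = c(RN = 0.03, `NA` = 0.04),
                             allow_floating = TRUE,
                             availability = availability_preset("limited"),
                             days = 365L,
                             shift_length = 8,
                             deployment_granularity = c("half", "full"),
                             master_seed = 1L,
                             multipliers = care_level_multipliers(),
                             max_headcount = 24,
                             max_blocks = 64L) {
  deployment_granularity <- match.arg(deployment_granularity)
  if (tolerance < 0 || tolerance >= 1) stop_config("tolerance must be in [0, 1)")
  if (any(absence_rates < 0 | absence_rates > 1)) {
    stop_config("absence rates must be probabilities")
  }
  if (days < 1L) stop_config("days must be >= 1")
  structure(
    list(tolerance = tolerance,
         absence_rates = absence_rates[ROLES],
         allow_floating = isTRUE(allow_floating),
         availability = availability,
         days = as.integer(days),
         shift_length = shift_length,
         deployment_granularity = deployment_granularity,
         master_seed = as.integer(master_seed),
         multipliers = multipliers,
         max_headcount = max_headcount,
         max_blocks = as.integer(max_blocks)),
    class = "simulator_config"
  )
}

block_hours_of <- function(config) {
  if (config$deployment_granularity == "half") config$shift_length / 2
  else config$shift_length
}

#' Draw short-notice absences for one rostered headcount
#'
#' Absence is binomial over the `2 x headcount` half-person slots with the
#' per-slot probability `rate`, reconciling fractional (half-person)
#' rosters with whole-person sickness; the expected absent headcount is
#' `headcount x rate`.
#'
#' @param headcount rostered headcount (non-negative multiple of 0.5).
#' @param rate per-slot absence probability in `[0, 1]`.
#' @param n number of draws.
#' @return Absent headcount(s) in half-person units.
#' @export
draw_absences <- function(headcount, rate, n = 1L) {
  if (rate < 0 || rate > 1) stop_config("absence rate must be in [0, 1]")
  if (headcount < 0) stop_input("headcount must be non-negative")
  slots <- round(2 * headcount)
  stats::rbinom(n, slots, rate) / 2
}

#' Classify staffing status of a unit-shift
#'
#' A unit-shift is `understaffed` iff its relative shortfall
#' `(required - available) / required` strictly exceeds the tolerance
#' (only possible when `required > 0`); `overstaffed` iff available hours
#' strictly exceed required hours; `adequate` otherwise. Fill actions are
#' triggered only for understaffed unit-shifts; zero requirement is never
#' understaffed.
#'
#' @param required,available non-negative hours (vectorised).
#' @param tolerance trigger tolerance in `[0, 1)`.
#' @return A list with `status` (character), `shortfall_hours`,
#'   `surplus_hours` and `triggered` (logical).
#' @export
#' @examples
#' classify_status(100, 84)$status # understaffed (16% > 15%)
#' classify_status(100, 86)$status # adequate (14% shortfall)
classify_status <- function(required, available, tolerance = 0.15) {
  if (any(required < 0) || any(available < 0)) {
    stop_input("required and available hours must be non-negative")
  }
  short <- pmax(required - available, 0)
  frac <- ifelse(required > 0, short / required, 0)
  status <- ifelse(frac > tolerance, "understaffed",
                   ifelse(available > required, "overstaffed", "adequate"))
  list(status = status,
       shortfall_hours = short,
       surplus_hours = pmax(available - required, 0),
       triggered = frac > tolerance)
}

#' Float staff between units of one specialty group
#'
#' Redeploys staff from units with a true surplus (available > required)
#' to triggered (understaffed) units of the same specialty group, in
#' half-shift blocks, role-matched. Recipients are processed in order of
#' decreasing absolute shortfall, donors in order of decreasing initial
#' surplus, ties broken by unit id; a donor never drops below its own
#' requirement, and a recipient stops once its availability reaches its
#' requirement (the final block may overshoot by less than one block).
#' Net float hours across the group are zero.
#'
#' @param required,available non-negative hours, one entry per unit of the
#'   group (single role, single shift).
#' @param triggered logical vector of fill triggers; defaults to the
#'   classification of `required` vs `available` at `tolerance`.
#' @param tolerance trigger tolerance (used only when `triggered` is NULL).
#' @param block_hours hours per deployable block.
#' @param unit_ids ids used for deterministic tie-breaking.
#' @return A list with `floated_in`, `floated_out` (hours per unit) and a
#'   `transfers` data frame (`from`, `to`, `hours`).
#' @export
float_staff <- function(required, available, triggered = NULL,
                        tolerance = 0.15, block_hours = 4,
                        unit_ids = NULL) {
  n <- length(required)
  if (length(available) != n) stop_input("length mismatch")
  if (is.null(unit_ids)) unit_ids <- sprintf("u%03d", seq_len(n))
  if (is.null(triggered)) {
    triggered <- classify_status(required, available, tolerance)$triggered
  }
  floated_in <- floated_out <- numeric(n)
  transfers <- list()
  surplus_blocks <- floor(pmax(available - required, 0) / block_hours + 1e-9)
  donors <- which(surplus_blocks >= 1)
  donors <- donors[order(-(available - required)[donors], unit_ids[donors])]
  recipients <- which(triggered & available < required)
  recipients <- recipients[order(-(required - available)[recipients],
                                 unit_ids[recipients])]
  blocks_left <- surplus_blocks
  for (r in recipients) {
    for (d in donors) {
      if (d == r) next
      need <- required[r] - (available[r] + floated_in[r])
      if (need <= 1e-9) break
      if (blocks_left[d] < 1) next
      take <- min(blocks_left[d], ceiling(need / block_hours - 1e-9))
      h <- take * block_hours
      floated_in[r] <- floated_in[r] + h
      floated_out[d] <- floated_out[d] + h
      blocks_left[d] <- blocks_left[d] - take
      transfers[[length(transfers) + 1L]] <-
        data.frame(from = unit_ids[d], to = unit_ids[r], hours = h,
                   stringsAsFactors = FALSE)
    }
  }
  transfers <- if (length(transfers)) {
    do.call(rbind, transfers)
  } else {
    data.frame(from = character(), to = character(), hours = numeric(),
               stringsAsFactors = FALSE)
  }
  list(floated_in = floated_in, floated_out = floated_out,
       transfers = transfers)
}

#' Hire temporary staff for residual shortfalls
#'
#' For each unit the request is the minimum number of blocks covering its
#' residual shortfall. Each requested block is independently filled from
#' the bank with probability `p_bank`; blocks the bank does not fill are
#' re-requested once from the agency with probability `p_agency`. Hires
#' never exceed the requested blocks.
#'
#' @param shortfall_hours residual shortfall per unit (hours, >= 0).
#' @param p_bank,p_agency fulfilment probabilities for this role, shift
#'   and weekday.
#' @param block_hours hours per block.
#' @param u_bank,u_agency optional uniform matrices (units x blocks) so
#'   callers can supply common random numbers; drawn internally otherwise.
#' @return A list with `bank_hours`, `agency_hours` and
#'   `requested_blocks`, each per unit.
#' @export
hire_temporary <- function(shortfall_hours, p_bank, p_agency,
                           block_hours = 4, u_bank = NULL, u_agency = NULL) {
  n <- length(shortfall_hours)
  req_blocks <- as.integer(ceiling(pmax(shortfall_hours, 0) / block_hours - 1e-9))
  bmax <- max(req_blocks, 1L)
  if (is.null(u_bank)) u_bank <- matrix(stats::runif(n * bmax), n, bmax)
  if (is.null(u_agency)) u_agency <- matrix(stats::runif(n * bmax), n, bmax)
  if (ncol(u_bank) < max(req_blocks) || ncol(u_agency) < max(req_blocks)) {
    stop_config("requested blocks exceed the engine block capacity (",
                ncol(u_bank), ")")
  }
  bank <- agency <- integer(n)
  for (i in which(req_blocks > 0L)) {
    j <- seq_len(req_blocks[i])
    bfill <- u_bank[i, j] < p_bank
    afill <- !bfill & u_agency[i, j] < p_agency
    bank[i] <- sum(bfill)
    agency[i] <- sum(afill)
  }
  list(bank_hours = bank * block_hours, agency_hours = agency * block_hours,
       requested_blocks = req_blocks)
}

#' Resolve the fills of one shift for one role
#'
#' Pure per-shift resolution: classify against the tolerance, float within
#' specialty groups (if allowed), then hire bank and agency blocks for
#' residual shortfalls of triggered units. `available` is rostered minus
#' absent hours; `achieved = available - floated_out + floated_in + bank +
#' agency`.
#'
#' @param required,available non-negative hours per unit (single role).
#' @param group specialty-group label per unit; floats never cross groups.
#' @param tolerance trigger tolerance.
#' @param block_hours hours per deployable block.
#' @param allow_float whether floating is permitted.
#' @param p_bank,p_agency fulfilment probabilities.
#' @param u_bank,u_agency optional uniform matrices (units x blocks).
#' @param unit_ids ids for deterministic tie-breaking.
#' @return A list with `floated_in`, `floated_out`, `bank_hours`,
#'   `agency_hours`, `achieved`, `status_before`, `status_after`.
#' @export
resolve_shift <- function(required, available, group,
                          tolerance = 0.15, block_hours = 4,
                          allow_float = TRUE, p_bank = 0, p_agency = 0,
                          u_bank = NULL, u_agency = NULL, unit_ids = NULL) {
  n <- length(required)
  if (is.null(unit_ids)) unit_ids <- sprintf("u%03d", seq_len(n))
  st0 <- classify_status(required, available, tolerance)
  floated_in <- floated_out <- numeric(n)
  if (allow_float && any(st0$triggered)) {
    for (g in unique(group)) {
      idx <- which(group == g)
      if (length(idx) < 2L || !any(st0$triggered[idx])) next
      fl <- float_staff(required[idx], available[idx],
                        triggered = st0$triggered[idx],
                        block_hours = block_hours, unit_ids = unit_ids[idx])
      floated_in[idx] <- fl$floated_in
      floated_out[idx] <- fl$floated_out
    }
  }
  after_float <- available - floated_out + floated_in
  residual <- ifelse(st0$triggered, pmax(required - after_float, 0), 0)
  h <- hire_temporary(residual, p_bank, p_agency, block_hours,
                      u_bank, u_agency)
  achieved <- after_float + h$bank_hours + h$agency_hours
  st1 <- classify_status(required, achieved, tolerance)
  list(floated_in = floated_in, floated_out = floated_out,
       bank_hours = h$bank_hours, agency_hours = h$agency_hours,
       achieved = achieved,
       status_before = st0$status, status_after = st1$status)
}

# absence counts from slot-level uniforms (monotone coupling: the same
# slot uniform decides the same person-slot under every staffing plan)
absent_slots_from_uniforms <- function(U, slots, rate) {
  if (any(slots > ncol(U))) {
    stop_config("rostered headcount exceeds engine slot capacity; raise ",
                "max_headcount")
  }
  rowSums((U < rate) & (col(U) <= slots))
}

weekday_of <- function(day) (as.integer(day) - 1L) %% 7L + 1L

# engine internals shared by run_shift() and run_scenario(): resolve one
# (day, shift) for both roles given precomputed demand and uniforms
shift_step <- function(req, rostered_hours, slots, Uabs, Ubank, Uagency,
                       group, unit_ids, wd, shift, config) {
  bh <- block_hours_of(config)
  out <- list()
  for (role in ROLES) {
    rate <- config$absence_rates[[role]]
    a_slots <- absent_slots_from_uniforms(Uabs[, role, ], slots[, role], rate)
    absent_hours <- a_slots * config$shift_length / 2
    available <- rostered_hours[, role] - absent_hours
    pb <- config$availability$lookup["bank", role, shift, wd]
    pa <- config$availability$lookup["agency", role, shift, wd]
    res <- resolve_shift(req[, role], available, group,
                         tolerance = config$tolerance, block_hours = bh,
                         allow_float = config$allow_floating,
                         p_bank = pb, p_agency = pa,
                         u_bank = Ubank[, role, ], u_agency = Uagency[, role, ],
                         unit_ids = unit_ids)
    res$absent_hours <- absent_hours
    out[[role]] <- res
  }
  out
}

# per-day uniform draws, identical across plans and availability scenarios
day_uniforms <- function(seed, day, n, config) {
  S <- round(2 * config$max_headcount)
  B <- config$max_blocks
  Uabs <- with_seed(
    mix_seed(seed, .PURPOSE[["absence"]], day),
    array(stats::runif(n * 2 * 3 * S), dim = c(n, 2, 3, S),
          dimnames = list(NULL, ROLES, SHIFTS, NULL))
  )
  Uav <- with_seed(
    mix_seed(seed, .PURPOSE[["availability"]], day),
    array(stats::runif(n * 2 * 2 * 3 * B), dim = c(n, 2, 2, 3, B),
          dimnames = list(NULL, c("bank", "agency"), ROLES, SHIFTS, NULL))
  )
  list(absence = Uabs, availability = Uav)
}

est_arrays <- function(establishment, unit_ids, config) {
  hc <- array(0, dim = c(length(unit_ids), 2, 3),
              dimnames = list(unit_ids, ROLES, SHIFTS))
  for (i in seq_len(nrow(establishment))) {
    hc[establishment$unit_id[i], establishment$role[i],
       establishment$shift[i]] <- establishment$headcount[i]
  }
  list(headcount = hc, hours = hc * config$shift_length,
       slots = round(2 * hc))
}

#' Simulate a single shift across all units of a hospital
#'
#' Composes demand draws, absence draws, shortfall classification,
#' floating, and bank/agency hires for one (day, shift), returning the
#' filled ledger rows. Uses the same sub-streams as [run_scenario()], so
#' the rows equal the corresponding rows of a full run under the same
#' master seed.
#'
#' @param hospital a `hospital_profile`.
#' @param day day index.
#' @param shift `"early"`, `"late"` or `"night"`.
#' @param establishment an [build_establishment()] plan covering all units.
#' @param config a [simulator_config()].
#' @return A data frame of ledger rows (one per unit x role).
#' @export
run_shift <- function(hospital, day, shift = SHIFTS, establishment,
                      config = simulator_config()) {
  shift <- match.arg(shift)
  units <- all_units(hospital)
  n <- length(units)
  unit_ids <- vapply(units, `[[`, "", "unit_id")
  group <- vapply(units, `[[`, "", "specialty_group")
  dem <- simulate_demand(hospital, as.integer(day), config$master_seed,
                         config$multipliers)
  est <- est_arrays(establishment, unit_ids, config)
  U <- day_uniforms(config$master_seed, day, n, config)
  s <- match(shift, SHIFTS)
  req <- dem$required[, , s, 1L, drop = FALSE]
  dim(req) <- c(n, 2); dimnames(req) <- list(NULL, ROLES)
  res <- shift_step(req, est$hours[, , s], est$slots[, , s],
                    U$absence[, , s, , drop = TRUE],
                    U$availability[, "bank", , s, , drop = TRUE],
                    U$availability[, "agency", , s, , drop = TRUE],
                    group, unit_ids, weekday_of(day), shift, config)
  rows <- lapply(ROLES, function(role) {
    r <- res[[role]]
    data.frame(
      unit_id = unit_ids, specialty_group = group,
      day = as.integer(day), shift = shift, role = role,
      census = dem$census[, 1L],
      required_hours = req[, role],
      rostered_hours = est$hours[, role, s],
      absent_hours = r$absent_hours,
      floated_out_hours = r$floated_out,
      floated_in_hours = r$floated_in,
      bank_hours = r$bank_hours,
      agency_hours = r$agency_hours,
      achieved_hours = r$achieved,
      status_before = r$status_before,
      status_after = r$status_after,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run a full staffing scenario for one hospital
#'
#' Simulates `config$days` days of three shifts for every unit under one
#' staffing plan and one availability scenario, and returns the complete
#' shift ledger. With a shared master seed, demand and absence slot
#' uniforms are identical across plans and availability scenarios (common
#' random numbers): only the fill behaviour differs.
#'
#' @param hospital a `hospital_profile`.
#' @param plan a plan kind (`"flexible"`, `"standard"`, `"resilient"`) or
#'   a prebuilt [build_establishment()] plan.
#' @param config a [simulator_config()].
#' @return A data frame of class `simulation_result`, one row per
#'   unit x day x shift x role, with attributes `plan`, `availability`,
#'   `hospital_id`, `master_seed` and `config`.
#' @export
run_scenario <- function(hospital, plan = "standard",
                         config = simulator_config(), .demand = NULL) {
  if (inherits(hospital, "hospital_set")) {
    if (length(hospital$hospitals) != 1L) {
      stop_input("run_scenario() simulates one hospital; iterate over ",
                 "hospital_set$hospitals or use run_experiment_grid()")
    }
    hospital <- hospital$hospitals[[1L]]
  }
  if (inherits(plan, "establishment_plan")) {
    establishment <- plan
    plan_name <- establishment$plan[1L]
  } else {
    plan_name <- match.arg(plan, PLAN_KINDS)
    establishment <- build_establishment(
      hospital, plan_name, config$master_seed,
      shift_length = config$shift_length, multipliers = config$multipliers
    )
  }
  units <- all_units(hospital)
  n <- length(units)
  unit_ids <- vapply(units, `[[`, "", "unit_id")
  group <- vapply(units, `[[`, "", "specialty_group")
  days <- config$days
  dem <- .demand %||% simulate_demand(hospital, seq_len(days),
                                      config$master_seed, config$multipliers)
  if (length(dem$day_index) != days) {
    stop_input("precomputed demand does not cover the configured days")
  }
  est <- est_arrays(establishment, unit_ids, config)
  if (any(est$slots > 2 * config$max_headcount)) {
    stop_config("establishment headcount exceeds max_headcount")
  }

  dims <- c(n, 2, 3, days)
  absent <- fin <- fout <- bank <- agency <- achieved <- array(0, dims)
  st_before <- st_after <- array("", dims)
  for (day in seq_len(days)) {
    U <- day_uniforms(config$master_seed, day, n, config)
    wd <- weekday_of(day)
    for (s in 1:3) {
      req <- dem$required[, , s, day, drop = FALSE]
      dim(req) <- c(n, 2); dimnames(req) <- list(NULL, ROLES)
      res <- shift_step(req, est$hours[, , s], est$slots[, , s],
                        U$absence[, , s, , drop = TRUE],
                        U$availability[, "bank", , s, , drop = TRUE],
                        U$availability[, "agency", , s, , drop = TRUE],
                        group, unit_ids, wd, SHIFTS[s], config)
      for (ri in 1:2) {
        r <- res[[ROLES[ri]]]
        absent[, ri, s, day] <- r$absent_hours
        fin[, ri, s, day] <- r$floated_in
        fout[, ri, s, day] <- r$floated_out
        bank[, ri, s, day] <- r$bank_hours
        agency[, ri, s, day] <- r$agency_hours
        achieved[, ri, s, day] <- r$achieved
        st_before[, ri, s, day] <- r$status_before
        st_after[, ri, s, day] <- r$status_after
      }
    }
  }

  idx <- expand.grid(unit = seq_len(n), role = 1:2, shift = 1:3,
                     day = seq_len(days), KEEP.OUT.ATTRS = FALSE)
  rost <- est$hours[cbind(idx$unit, idx$role, idx$shift)]
  out <- data.frame(
    unit_id = unit_ids[idx$unit],
    specialty_group = group[idx$unit],
    day = idx$day,
    shift = SHIFTS[idx$shift],
    role = ROLES[idx$role],
    census = dem$census[cbind(idx$unit, idx$day)],
    required_hours = dem$required[cbind(idx$unit, idx$role, idx$shift, idx$day)],
    rostered_hours = rost,
    absent_hours = absent[cbind(idx$unit, idx$role, idx$shift, idx$day)],
    floated_out_hours = fout[cbind(idx$unit, idx$role, idx$shift, idx$day)],
    floated_in_hours = fin[cbind(idx$unit, idx$role, idx$shift, idx$day)],
    bank_hours = bank[cbind(idx$unit, idx$role, idx$shift, idx$day)],
    agency_hours = agency[cbind(idx$unit, idx$role, idx$shift, idx$day)],
    achieved_hours = achieved[cbind(idx$unit, idx$role, idx$shift, idx$day)],
    status_before = st_before[cbind(idx$unit, idx$role, idx$shift, idx$day)],
    status_after = st_after[cbind(idx$unit, idx$role, idx$shift, idx$day)],
    stringsAsFactors = FALSE
  )
  attr(out, "plan") <- plan_name
  attr(out, "availability") <- config$availability$name
  attr(out, "hospital_id") <- hospital$hospital_id
  attr(out, "master_seed") <- config$master_seed
  attr(out, "config") <- config
  class(out) <- c("simulation_result", "data.frame")
  out
}

#' Summarise a simulation result per unit-day
#'
#' Aggregates the shift ledger to unit-days: achieved and required hours
#' (total and per role), temporary (bank + agency) hours, the day's census
#' (patient days are counted once per unit-day), and hours per patient
#' day (`NA` where the census is zero).
#'
#' @param result a [run_scenario()] result.
#' @return A data frame with one row per unit x day.
#' @export
unit_day_summary <- function(result) {
  key <- paste(result$unit_id, result$day, sep = "\r")
  first <- !duplicated(key)
  lev <- key[first]
  achieved <- rowsum(result$achieved_hours, key)[lev, ]
  required <- rowsum(result$required_hours, key)[lev, ]
  temp <- rowsum(result$bank_hours + result$agency_hours, key)[lev, ]
  rn <- rowsum(ifelse(result$role == "RN", result$achieved_hours, 0), key)[lev, ]
  na_h <- rowsum(ifelse(result$role == "NA", result$achieved_hours, 0), key)[lev, ]
  out <- data.frame(
    unit_id = result$unit_id[first],
    day = result$day[first],
    census = result$census[first],
    achieved_hours = achieved,
    required_hours = required,
    achieved_rn_hours = rn,
    achieved_na_hours = na_h,
    temporary_hours = temp,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out$achieved_hppd <- ifelse(out$census > 0,
                              out$achieved_hours / out$census, NA_real_)
  out$temporary_hppd <- ifelse(out$census > 0,
                               out$temporary_hours / out$census, NA_real_)
  out
}
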