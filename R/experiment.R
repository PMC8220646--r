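# Experiment orchestration: the plans x availability grid over all
# hospitals, unweighted cross-hospital averages, and the report tables.

#' Experiment configuration
#'
#' Bundles every parameter block of a full experiment: the synthetic
#' hospital generator, the simulator, costs, effect estimates, the grid of
#' plans and availability scenarios, the analysis variants and the master
#' seed. Incremental comparisons are always made against the reference
#' plan (standard by default), and results are averaged across hospitals
#' without weighting.
#'
#' @param generator generator block, see [default_gen_config()].
#' @param plans staffing plans to run.
#' @param availabilities availability preset names to run.
#' @param reference_plan plan against which low staffing is judged.
#' @param variants analysis variants to evaluate.
#' @param days simulated days per scenario.
#' @param costs a [cost_parameters()].
#' @param effects an [effect_estimates()].
#' @param tolerance,absence_rates,allow_floating,shift_length simulator
#'   settings, see [simulator_config()].
#' @param multipliers a [care_level_multipliers()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(generator = default_gen_config(),
                              plans = PLAN_KINDS,
                              availabilities = c("none", "limited",
                                                 "higher", "unlimited"),
                              reference_plan = "standard",
                              variants = c("low_staffing_only",
                                           "including_temporary_effects"),
                              days = 365L,
                              costs = cost_parameters(),
                              effects = effect_estimates(),
                              tolerance = 0.15,
                              absence_rates = c(RN = 0.03, `NA` = 0.04),
                              allow_floating = TRUE,
                              shift_length = 8,
                              multipliers = care_level_multipliers()) {
  if (!reference_plan %in% plans) {
    stop_config("reference_plan must be one of the plans in the grid")
  }
  structure(
    list(generator = generator, plans = plans,
         availabilities = availabilities, reference_plan = reference_plan,
         variants = variants, days = as.integer(days), costs = costs,
         effects = effects, tolerance = tolerance,
         absence_rates = absence_rates, allow_floating = allow_floating,
         shift_length = shift_length, multipliers = multipliers),
    class = "experiment_config"
  )
}

#' Load an experiment configuration from YAML or JSON
#'
#' Reads a config file whose top-level blocks (`generator`, `grid`,
#' `costs`, `effects`, `simulator`) override the package defaults.
#' Unknown blocks are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- c("generator", "grid", "costs", "effects", "simulator")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_config("unknown config block(s): ", paste(bad, collapse = ", "))
  }
  args <- list()
  if (!is.null(raw$generator)) {
    args$generator <- utils::modifyList(default_gen_config(), raw$generator)
  }
  g <- raw$grid
  for (f in c("plans", "availabilities", "reference_plan", "variants",
              "days")) {
    if (!is.null(g[[f]])) args[[f]] <- g[[f]]
  }
  if (!is.null(raw$costs)) {
    cs <- cost_parameters()
    if (!is.null(raw$costs$hourly)) {
      cs$hourly[] <- as.matrix(raw$costs$hourly)
    }
    if (!is.null(raw$costs$excess_bed_day_cost)) {
      cs$excess_bed_day_cost <- raw$costs$excess_bed_day_cost
    }
    args$costs <- cs
  }
  if (!is.null(raw$effects)) {
    args$effects <- do.call(effect_estimates, raw$effects)
  }
  s <- raw$simulator
  for (f in c("tolerance", "allow_floating", "shift_length")) {
    if (!is.null(s[[f]])) args[[f]] <- s[[f]]
  }
  if (!is.null(s$absence_rates)) {
    args$absence_rates <- unlist(s$absence_rates)
  }
  do.call(experiment_config, args)
}

run_one_cell <- function(hospital, plan, avail_name, config, master_seed,
                         .demand = NULL) {
  sim_cfg <- simulator_config(
    tolerance = config$tolerance,
    absence_rates = config$absence_rates,
    allow_floating = config$allow_floating,
    availability = availability_preset(avail_name),
    days = config$days,
    shift_length = config$shift_length,
    master_seed = master_seed,
    multipliers = config$multipliers
  )
  run_scenario(hospital, plan, sim_cfg, .demand = .demand)
}

#' Run the full experiment grid
#'
#' For every hospital and availability scenario, runs all staffing plans
#' under common random numbers (the per-hospital master seed is shared by
#' every cell), summarises achieved staffing and daily cost per cell, and
#' evaluates the incremental comparisons (standard vs flexible, resilient
#' vs standard) for each analysis variant. Hospital-level results are
#' retained and cross-hospital averages are unweighted, with incremental
#' ratios recomputed from the averaged cost and outcome deltas.
#'
#' @param config an [experiment_config()].
#' @param seed integer master seed; recorded in the manifest.
#' @return A list of class `experiment_result` with `cells` (per-cell
#'   achieved staffing/cost summaries), `comparisons` (per hospital),
#'   `comparison_averages` (cross-hospital), and a `manifest`.
#' @export
run_experiment_grid <- function(config = experiment_config(), seed = 1L) {
  hs <- generate_hospital(config$generator, seed)
  cells <- list()
  comparisons <- list()
  for (hi in seq_along(hs$hospitals)) {
    hosp <- hs$hospitals[[hi]]
    hseed <- mix_seed(seed, 131L, hi)
    # demand is plan- and availability-independent: draw it once per
    # hospital and share it across every cell (common random numbers)
    dem <- simulate_demand(hosp, seq_len(config$days), hseed,
                           config$multipliers)
    for (av in config$availabilities) {
      runs <- lapply(stats::setNames(config$plans, config$plans),
                     function(p) run_one_cell(hosp, p, av, config, hseed,
                                              .demand = dem))
      for (p in config$plans) {
        cs <- staffing_cost_summary(runs[[p]], config$costs)
        ud <- unit_day_summary(runs[[p]])
        ok <- ud[ud$census > 0, ]
        cells[[length(cells) + 1L]] <- data.frame(
          hospital = hosp$hospital_id, availability = av, plan = p,
          cost_per_patient_day = cs$cost_per_patient_day,
          rn_hppd = sum(ok$achieved_rn_hours) / sum(ok$census),
          na_hppd = sum(ok$achieved_na_hours) / sum(ok$census),
          mean_achieved_hppd = sum(ok$achieved_hours) / sum(ok$census),
          staff_cost_total = cs$total_cost,
          patient_days = cs$patient_days,
          prop_understaffed_shifts = mean(
            runs[[p]]$status_after == "understaffed"),
          stringsAsFactors = FALSE
        )
      }
      ref <- config$reference_plan
      pairs <- list()
      if (all(c("flexible", ref) %in% config$plans)) {
        pairs <- c(pairs, list(c(ref, "flexible")))
      }
      if (all(c("resilient", ref) %in% config$plans)) {
        pairs <- c(pairs, list(c("resilient", ref)))
      }
      for (pr in pairs) {
        for (v in config$variants) {
          cmp <- evaluate_comparison(runs[[pr[1]]], runs[[pr[2]]],
                                     runs[[ref]], config$costs,
                                     config$effects, v)
          comparisons[[length(comparisons) + 1L]] <- data.frame(
            hospital = hosp$hospital_id, availability = av, variant = v,
            comparison = paste(pr[1], "vs", pr[2]),
            staff_cost_pct = cmp$staff_cost_pct,
            bed_days_pct = cmp$bed_days_pct,
            deaths_pct = cmp$deaths_pct,
            delta_staff_cost = cmp$economics$delta_staff_cost,
            delta_deaths = cmp$economics$delta_deaths,
            delta_bed_days = cmp$economics$delta_bed_days,
            admissions = cmp$economics$admissions,
            nn = cmp$economics$nn,
            staff_cost_per_life = cmp$economics$staff_cost_per_life,
            net_cost_per_life = cmp$economics$net_cost_per_life,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  comparisons <- do.call(rbind, comparisons)
  comparison_averages <- average_comparisons(comparisons, config$costs)
  manifest <- list(
    package = "wardflex",
    package_version = as.character(utils::packageVersion("wardflex")),
    seed = as.integer(seed),
    days = config$days,
    n_hospitals = length(hs$hospitals),
    n_units = length(all_units(hs)),
    plans = config$plans,
    availabilities = config$availabilities,
    variants = config$variants,
    reference_plan = config$reference_plan,
    effects = unclass(config$effects),
    hourly_costs = config$costs$hourly,
    excess_bed_day_cost = config$costs$excess_bed_day_cost,
    multipliers = config$multipliers$hours
  )
  structure(
    list(cells = cells, comparisons = comparisons,
         comparison_averages = comparison_averages, manifest = manifest),
    class = "experiment_result"
  )
}

# unweighted cross-hospital averages; incremental ratios recomputed from
# the averaged deltas (average delta cost / average delta outcome)
average_comparisons <- function(comparisons, costs) {
  if (is.null(comparisons) || nrow(comparisons) == 0L) {
    return(comparisons)
  }
  key <- interaction(comparisons$availability, comparisons$variant,
                     comparisons$comparison, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    d <- comparisons[key == k, ]
    ds <- mean(d$delta_staff_cost)
    dd <- mean(d$delta_deaths)
    db <- mean(d$delta_bed_days)
    adm <- mean(d$admissions)
    ce <- cost_effectiveness(ds, dd, db, adm, costs)
    data.frame(
      availability = d$availability[1], variant = d$variant[1],
      comparison = d$comparison[1],
      n_hospitals = nrow(d),
      staff_cost_pct = mean(d$staff_cost_pct),
      bed_days_pct = mean(d$bed_days_pct),
      deaths_pct = mean(d$deaths_pct),
      delta_staff_cost = ds, delta_deaths = dd, delta_bed_days = db,
      admissions = adm,
      nn = ce$nn,
      staff_cost_per_life = ce$staff_cost_per_life,
      net_cost_per_life = ce$net_cost_per_life,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", nrow(x$cells), " grid cells, ",
      if (is.null(x$comparisons)) 0L else nrow(x$comparisons),
      " comparisons (seed ", x$manifest$seed, ")\n", sep = "")
  invisible(x)
}

#' Write report tables of an experiment to CSV and JSON
#'
#' Writes the achieved-staffing table (`cells.csv`), the per-hospital and
#' cross-hospital comparison tables (`comparisons.csv`,
#' `comparison_averages.csv`) and a JSON manifest recording the seed,
#' problem sizes and every parameter value used. Column order is fixed, so
#' repeated runs of the same configuration are byte-stable.
#'
#' @param results an [run_experiment_grid()] result.
#' @param dir output directory (created if needed; must be writable).
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(results, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L) {
    stop("output directory not writable: ", dir)
  }
  paths <- c(
    cells = file.path(dir, "cells.csv"),
    comparisons = file.path(dir, "comparisons.csv"),
    comparison_averages = file.path(dir, "comparison_averages.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  cell_cols <- c("hospital", "availability", "plan", "cost_per_patient_day",
                 "rn_hppd", "na_hppd", "mean_achieved_hppd",
                 "staff_cost_total", "patient_days",
                 "prop_understaffed_shifts")
  cmp_cols <- c("hospital", "availability", "variant", "comparison",
                "staff_cost_pct", "bed_days_pct", "deaths_pct",
                "delta_staff_cost", "delta_deaths", "delta_bed_days",
                "admissions", "nn", "staff_cost_per_life",
                "net_cost_per_life")
  empty <- function(cols) {
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  utils::write.csv(results$cells %||% empty(cell_cols), paths["cells"],
                   row.names = FALSE)
  utils::write.csv(results$comparisons %||% empty(cmp_cols),
                   paths["comparisons"], row.names = FALSE)
  utils::write.csv(results$comparison_averages %||%
                     empty(setdiff(cmp_cols, "hospital")),
                   paths["comparison_averages"], row.names = FALSE)
  jsonlite::write_json(results$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
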