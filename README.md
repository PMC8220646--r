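# wardflex

Stochastic simulation and economic evaluation of hospital nurse staffing
plans.

## The problem

Hospitals must decide how many nurses to roster on each inpatient unit in
advance (the baseline roster) and how to respond on the day when demand —
driven by patient census, acuity/dependency and 1:1 specialing — outstrips
the staff who turn up. Flexible responses include *floating* staff from
overstaffed units within the same specialty group and hiring temporary
staff from an internal *bank* or an external *agency*, whose short-notice
availability is uncertain. Plans that roster few staff and lean on
flexible deployment look efficient, but if temporary staff cannot be
found, shifts are left short and patients are exposed to low staffing,
which lengthens stays and increases mortality risk.

`wardflex` is for health-services and nursing-workforce researchers who
want to study this trade-off quantitatively. It simulates, shift by shift,
hospital units that move between being understaffed, adequately staffed
and overstaffed, under three baseline rostering plans crossed with four
temporary-staff availability scenarios, and converts the achieved staffing
into costs and patient outcomes.

## The model in brief

* **Demand.** Daily required care hours per unit are
  `sum over care levels (patients at level x care hours per level) +
  24 h x specialing patients`, split across early/late/night shifts by
  unit-specific weights and between registered nurses (RN) and assistants
  (NA) by the unit's skill mix. Days are independent draws (no serial
  correlation).
* **Plans.** Baselines are set from a 20-day establishment sample of daily
  demand: *flexible* targets `0.8 x mean`, *standard* the `mean`,
  *resilient* the nearest-rank 90th percentile. Headcounts are rostered in
  half-person steps.
* **Shift engine.** Short-notice sickness is binomial over half-person
  slots (RN 3%, NA 4%). A unit-shift whose relative shortfall exceeds the
  15% tolerance triggers fills: role-matched floating within the specialty
  group first, then bank and finally agency requests in half-shift blocks,
  each block fulfilled with a probability depending on source, role, shift
  and weekday. Scenarios sharing a master seed share demand and absence
  streams (common random numbers).
* **Economics.** A unit-day is *low-staffed* when its achieved hours per
  patient day (HPPD) fall below that unit's mean under the standard plan,
  and *high-temporary* when bank+agency hours exceed 1.5 h per patient
  day. Exposure differences translate into deaths
  (`baseline risk x admissions x (RR - 1) x delta exposure days`) and bed
  days, then into `NNT = 1/ARR` (or NNH), staff cost per life saved, and
  net cost per life saved after valuing bed days at £337 each.
* **Synthetic hospitals.** No unit-level hospital data are published, so a
  generator supplies 3 hospitals x 27 units whose required-hours
  distributions are calibrated to the reported shape statistics (median
  per-unit skewness ~0.6, median excess kurtosis ~0.7, mean census ~22.9).
  Effect estimates and pay rates ship as clearly-labelled illustrative
  configuration.

## Worked example

```r
library(wardflex)
hs   <- generate_hospital(seed = 1)      # 3 hospitals x 27 units
hosp <- hs$hospitals[[1]]

cfg <- simulator_config(days = 365, master_seed = 1,
                        availability = availability_preset("limited"))
std <- run_scenario(hosp, "standard",  cfg)
res <- run_scenario(hosp, "resilient", cfg)

cs <- staffing_cost_summary(std)
ud <- unit_day_summary(std); ok <- ud[ud$census > 0, ]
round(cs$cost_per_patient_day, 2)                      # 172.37
round(sum(ok$achieved_rn_hours) / sum(ok$census), 2)   # 3.02 RN HPPD
round(sum(ok$achieved_na_hours) / sum(ok$census), 2)   # 3.51 NA HPPD

evaluate_comparison(res, std, std)$economics
#> <economic_result> delta deaths -120.66, NNT 388,
#>   staff cost/life 61580, net cost/life 50347
```

Reading the output: under limited temporary-staff availability the
standard plan costs £172 per patient day and achieves 3.0 RN and 3.5 NA
hours per patient day. Switching this hospital to the resilient plan
raises staff costs by 18.4%, averts ~121 deaths a year in the simulated
population (one per 388 admissions), and — because shorter stays offset
part of the staff cost — costs £50,347 net per life saved versus £61,580
in staff costs alone. Absolute levels depend on the illustrative cost and
effect configuration; the qualitative pattern (higher baselines cost more,
save lives, and look better once bed days are valued) is the model's
central behaviour.

The full 3-plan x 4-availability grid, cross-hospital averages, report
tables and the parameter-perturbation sensitivity grid come from
`run_experiment_grid()`, `write_report_tables()` and `sensitivity_grid()`.

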