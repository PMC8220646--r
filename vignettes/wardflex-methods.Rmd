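---
title: "Methods: simulating flexible ward staffing and its economics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating flexible ward staffing and its economics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardflex)
```

## The model

`wardflex` simulates hospital inpatient units as they move between being
understaffed, adequately staffed and overstaffed. Each simulated day,
every unit draws a patient mix — census, counts in five acuity/dependency
care levels, and 1:1 specialing patients — and converts it into required
nursing hours. Against this demand stands the baseline roster of one of
three staffing plans, depleted by short-notice sickness and repaired by a
fixed sequence of flexible responses: floating within the specialty
group, then bank hires, then agency hires. The achieved staffing ledger
feeds a health-economic layer that prices the staffing and converts
differences in exposure to low (and to high temporary) staffing into
deaths, bed days, numbers needed to treat or harm, and net cost per life
saved.

Key structural assumptions:

* **Independent days.** Demand is redrawn independently each day; there is
  no seasonality and no serial correlation. The model estimates the
  average behaviour of a fixed roster against stationary demand, not a
  forecast.
* **One patient mix per day.** The three shifts of a day share the day's
  draw, with hours split by unit-specific shift weights. Patient days are
  counted once per unit-day, so per-patient-day quantities are daily.
* **Role matching.** Registered nurses substitute only for registered
  nurses and assistants only for assistants, in every fill mechanism.
* **Half-shift currency.** People are deployed in half-shift blocks
  (4 h at the default 8 h shift length): rosters are set in half-person
  steps and every float or temporary hire moves whole blocks.
* **No efficiency penalty.** Floated and temporary staff count at face
  value; an adverse effect of heavy temporary staffing enters only through
  the secondary analysis variant of the economics layer.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `tolerance` | 0.15 | fraction | relative shortfall that triggers fills; the tolerance used by workload-tool practice |
| `absence_rates` | RN 0.03, NA 0.04 | probability/shift | short-notice sickness per half-person slot |
| `shift_length` | 8 | hours | three shifts cover the day |
| care-level multipliers | 3, 4.5, 5.5, 9, 14 | h/patient/day | illustrative acuity-tool scale; configurable |
| `specialing_hours` | 24 | h/patient/day | 1:1 care, assigned to assistants by default |
| plan targets | 0.8 × mean / mean / P90 | — | flexible, standard, resilient; applied to a 20-day establishment sample |
| hourly costs | RN 27/25.5/28; NA 17/16/17.6 | currency/h | substantive/bank/agency; bank below substantive (reduced pension), agency a capped ~10% above bank |
| unsocial multipliers | night 1.30; weekend 1.45 | factor | applied to all hours on the shift |
| `excess_bed_day_cost` | 337 | currency | national reference cost of one excess bed day |
| `rr_death_per_low_day` | 1.03 (CI 1.01–1.05) | risk ratio/day | illustrative, echoed in every manifest |
| `rr_death_high_temp` | 1.08 | risk ratio/day | secondary analysis only |
| `high_temp_threshold` | 1.5 | h/patient-day | strict inequality |
| `baseline_mortality_risk` | 0.035 | per admission | with `baseline_los_days` 5 |

The agency premium deserves a note: the base case treats agency rates as
capped, roughly 10% above bank rates. The sensitivity grid exposes the
alternative assumptions (`agency_cost_plus_25`, `agency_equals_bank`,
`bank_equals_substantive`, `all_costs_plus_25`, bed-day cost +25%, the
mortality CI bounds, and `no_floating`, which is the only perturbation
that re-simulates).

## The synthetic hospital generator

No unit-level hospital dataset ships with the package; the generator
replaces it. Its defaults define the study conditions: 3 hospitals of 27
units (81 units), specialty groups of 9 units, beds 22–32, occupancy
0.81–0.91 so the mean census per unit-day is near 22.9.

Daily required hours arise structurally, not as direct draws: census is a
rounded truncated normal on `[0, beds]` (CV 0.10); a gamma daily acuity
factor (mean 1) tilts the unit's base care-level mix towards the
high-acuity levels through an exponential tilt on the multipliers'
z-scores; counts are multinomial given census and the tilted mix;
specialing is Poisson truncated at the census. Rare "surge" days
(probability 0.045) multiply or divide the acuity factor by 1.8 with
equal probability, fattening both tails.

The free shape constants (median gamma shape 44, between-unit log-sd 1.5,
tilt 0.77, the surge pair) were calibrated once so that, at the default
scale (81 units × 365 days), the cross-unit median of the per-unit
adjusted Fisher–Pearson sample skewness of daily required hours is close
to 0.6 and the median sample excess kurtosis close to 0.7, with a
realistic minority of strongly right-skewed units (about 10% above
skewness 1). These are the two statistics `scripts/acceptance.R`
recomputes. What the generator does *not* emulate: admission/discharge
dynamics, case-mix drift, seasonality, weekday demand patterns, or
correlation between neighbouring units. Passing tests therefore show that
the pipeline behaves correctly under stationary, independently-drawn
demand of realistic shape — not that it reproduces any particular
hospital.

## Numerical and procedural choices

* **Seeding.** One master seed spawns named sub-streams (establishment,
  demand, absence, availability) through an integer mixer whose products
  stay exact in doubles. Each (unit, day) demand draw has its own
  sub-seed, so a single day can be regenerated in isolation and every
  plan/availability cell of an experiment sees identical demand and
  absence randomness (common random numbers). Absence is coupled at the
  half-person-slot level: the same slot uniform decides the same person
  under every plan, which is what makes plan dominance exact when no
  fills run. Bank and agency block uniforms are likewise assigned per
  block regardless of outcome, making achieved hours monotone in the
  fulfilment probabilities.
* **Rounding.** Headcounts round to the nearest 0.5 person with ties up
  (`floor(2x + 0.5)/2`). The resilient percentile is nearest-rank
  (`ceiling(0.9 n)`-th order statistic), reproducible at n = 20.
* **Classification.** Understaffed iff `(required - available)/required >
  tolerance` (strict); overstaffed iff `available > required` (strict);
  zero requirement is never understaffed. Both exposure thresholds are
  strict as well.
* **Floating.** Recipients are processed in decreasing order of absolute
  shortfall, donors in decreasing order of initial surplus, ties broken
  by unit id; donors give only whole blocks of true surplus and never
  drop below their own requirement; recipients stop at requirement (the
  final block may overshoot by less than one block).
* **Fill target.** Once triggered, a unit is filled towards its full
  requirement, not merely back to the tolerance boundary: the tolerance
  is a trigger, not a target. Requests are the minimum number of blocks
  covering the shortfall; each block gets one bank attempt and, if
  unfilled, one agency attempt.
* **Costing.** Rostered hours are paid at substantive rates whether or
  not sickness occurs (salaried staff), floats redistribute rather than
  add cost, and bank/agency hours are paid as worked. The deaths formula
  is implemented in the standard linear excess-risk form; the compact
  published-style expression is available behind `literal = TRUE` for
  audit because, taken verbatim, it is dimensionally inconsistent.
* **Exposure weighting.** Exposure proportions are weighted by patient
  days and converted to per-admission exposure days through the baseline
  length of stay, matching the patient-level design of the longitudinal
  studies such effect estimates come from.
* **Degenerate inputs.** Zero-census distributions, zero-variance units
  (excluded from shape summaries with a warning), empty samples,
  zero-deaths comparisons (explicit no-effect result rather than a
  division blow-up) and one-unit specialty groups (warning: floating is
  vacuous) are all handled explicitly.
* **Interfaces.** The experiment layer is function-first:
  `run_experiment_grid()`, `write_report_tables()` and
  `read_experiment_config()` (YAML/JSON) are the entry points a script or
  scheduler would call; `scripts/acceptance.R` is a worked example of
  driving the package non-interactively.

## Problem sizes

The shipped tests run the full default grid (3 hospitals × 3 plans × 4
availability scenarios × 365 days, 27 units each) once, plus a 10-unit,
100-day hospital for the dominance and monotonicity properties, 1,000
randomized 2–3-unit toy instances against a straight-line re-implementation
of the fill rules, and five 81-unit × 365-day generator realisations for
the calibration check. These sizes were chosen so the whole suite
exercises every full-scale code path while remaining comfortable to run
repeatedly during development.

## Known limitations

* Absolute cost and outcome levels depend on illustrative configuration
  (pay rates, effect estimates, care-hour multipliers) and should be read
  qualitatively; every report manifest echoes the values used.
* The exposure definition counts unit-days strictly below the unit's
  standard-plan mean, weighting a 1% and a 20% shortfall equally. Combined
  with fill-to-full-requirement, this produces one counter-intuitive
  regime: when agency fulfilment is certain (the unlimited scenario), the
  flexible plan is topped up to requirement on most shifts, its achieved
  staffing converges onto the standard plan's, and its day-count exposure
  can fall marginally below the standard plan's — so the standard-vs-
  flexible comparison in that single column can show a small harm rather
  than a small benefit, and its cost advantage becomes knife-edge. The
  acceptance suite asserts the full qualitative pattern in every column
  and therefore documents this boundary honestly as a failing assertion
  rather than masking it. The effect is a joint property of the trigger
  threshold, the fill-to-requirement target and the day-count exposure
  metric; filling only back to the tolerance boundary would remove it but
  would contradict the fill-target design adopted above.
* Within-shift dynamics, staff identities, fatigue, and efficiency losses
  of floated/temporary staff are out of scope; the secondary analysis
  variant is the only channel for temporary-staffing harm.
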