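---
title: "Modelling the cost-utility of daily acute-stroke rehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-utility of daily acute-stroke rehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabcua)
```

## The decision problem

Acute stroke patients in Japan receive inpatient rehabilitation for about
30 days after onset. Some hospitals deliver it every day of the week;
most deliver it only on weekdays. Observational evidence (a large
national rehabilitation database) suggests daily rehabilitation raises the
odds of being functionally independent — modified Rankin Scale (mRS) 0–2 —
three months after onset, with an adjusted odds ratio of 1.62 for mRS0-2.
`rehabcua` asks what that difference is worth to the public payer: it
computes incremental costs, quality-adjusted life years (QALYs) and
incremental cost-effectiveness ratios (ICERs) for the 7-days-per-week
schedule against the conventional 5-/6-days-per-week schedule, under

* the **public healthcare payer's perspective** (medical costs only), and
* the **combined healthcare + long-term-care payer's perspective**
  (medical plus public long-term-care insurance costs),

judged against the Japanese willingness-to-pay threshold of 5,000,000
JPY/QALY (about \$37,913 at 131.88 JPY/USD).

## Model structure

### States and timing

The cohort (75-year-olds with a moderate-to-severe first stroke) is
simulated at monthly cycles over three coarse states: mRS0-2
(independent), mRS3-5 (disabled) and mRS6 (dead). The model enters at
month 3 after onset — when the 90-day outcome is observed — and runs to
month 60 in the base case: 58 trace points, 57 transitions. Months 1–3
(acute and convalescent hospital care) are identical between arms except
for the rehabilitation fees, so they carry the acute cost difference but
accrue no QALYs or long-term-care costs; accrual starts at month 4
(`econ$accrue_from_month`, exposed because the alternative — valuing
months 1–3 at the initial distribution — is defensible too and changes
absolute QALYs but not the sign of any increment).

The arms share one transition schedule. They differ only in

* the initial distribution: control 37.6 / 58.5 / 3.9 %; intervention
  mRS0-2 = 37.6 % × RR with the death share held equal and mRS3-5 taking
  the remainder (49.3 / 46.8 / 3.9 % at RR 1.31 — the construction rule is
  trusted over the two inconsistent printed roundings of the middle
  entry), and
* the weekly rehabilitation calendar used for acute-stage costing.

The risk ratio comes from the adjusted odds ratio via
`RR = OR / (1 − p0 + p0·OR)` at the control-arm baseline risk
`p0 = 0.376`.

### Transitions and calibration

Disease-specific mortality is anchored to a general-population life
table: in each cycle, `P(state → dead)` is the monthly general-population
death probability at the cohort's attained age multiplied by a
state-specific mortality risk ratio (`rr_mort_mrs02`, `rr_mort_mrs35`).
Annual probabilities convert to monthly ones as
`1 − (1 − q)^(1/12)`, which inverts exactly under 12-cycle compounding.
Two state-specific ratios are used rather than one shared ratio because a
single ratio cannot simultaneously fit a survival curve and an
independence-among-survivors target; a config switch (`tie_ratios`) ties
them when desired.

Recovery (mRS3-5 → mRS0-2 at `p_recover_monthly` per cycle) is allowed
only while the destination month is within the first year after onset
(destination month ≤ `recovery_window_months = 12`, i.e. the first nine
cycles). The wording "the first year" could also be read as the first
twelve cycles (months ≤ 15); the window is a config parameter so either
reading is available. A worsening transition (mRS0-2 → mRS3-5) is carried
as a calibratable parameter but frozen at 0 by default: the published
model structure only guarantees the recovery and death arrows.

Attained age is indexed by cycles since model entry
(`age = 75 + floor((t − 1)/12)`): the cohort is exactly 75 on entry, so
with unit risk ratios the model reproduces cumulative life-table survival
*exactly* at 12-cycle landmarks — the null-consistency identity the test
suite asserts to 1e-9. No half-cycle correction is applied; with monthly
cycles the correction is far below every other uncertainty in the model.

The free parameters are fitted by **calibration**: unweighted least
squares between model-predicted and target values (survival at landmark
months, and the proportion independent among survivors where given). The
optimiser is a deterministic coarse grid (10 points per dimension over
`rr ∈ [1, 20]`, `p ∈ [0, 0.2]`) followed by Nelder-Mead refinement on
logistic box-transformed coordinates (relative tolerance 1e-12, one
restart; the start is nudged 2 % inside the box because a start exactly on
a bound saturates the transform). Calibration is deterministic. A fit
whose residual sum of squares stays above `calibration$tol` (default
0.01) raises an error carrying the best-found parameters and residuals.

Parameter recovery is the primary evidence that this works: targets
generated by the forward model from known parameters are refit across
twenty random truths, and the truth is recovered within ±0.01 (typically
within 1e-4).

### Beyond year 5

For the 10-year scenario, cycles after month 60 reuse the fifth-year
non-mortality parameters (recovery is already zero there) while death
probabilities keep tracking attained-age life-table mortality times the
same risk ratios. `extend_schedule()` implements this and is verified to
coincide with building the longer schedule directly.

### Fine grades, costs and utilities

Coarse occupancy is split into grades 0:1:2 = 30.5:29.8:39.6 % and
3:4:5 = 37.5:36.9:25.6 %, held constant over the horizon. The printed
triples sum to 99.9 %, so they are renormalised to sum exactly to 1 —
probability conservation is non-negotiable. (One published table restates
the mRS3-5 split with the mRS0-2 numbers; the Methods values above are
used.)

**Acute medical cost.** Only acute-stage rehabilitation fees differ
between arms. Each delivered unit (20 min) costs \$18.6, plus \$2.41 in
onset-days 1–30, plus a further \$3.62 in onset-days 1–14, at 4.3
units/day for 30 days with day 1 the onset day. The onset weekday is
uniform over the week, so the weekday-only arm's expected cost is the
exact mean over the seven onset weekdays (a 14-day window always contains
10 weekdays; the 16-day tail contains 80/7 on average). This yields
\$2928 vs \$2092 — an incremental \$836.63 — and the cost is exactly
linear in every fee component and in units/day, which is what drives the
exact tornado scalings. Both surcharges attach to every delivered unit in
their windows with no cap; acute cost is not discounted (it occurs in
month 1).

**Long-term-care cost.** From month 4, each fine grade maps to a
care-needs level with a utilization rate (0 / 21.6 / 91.5 / 98.5 / 100 /
100 / 0 % for mRS0–6) and a monthly cost (\$219 / 376 / 806 for Support 1,
Support 2, Care 1; mRS4 mixes Care 2:3 = 60.8:39.2 % of \$1090/\$1596;
mRS5 mixes Care 4:5 = 61.0:39.0 % of \$1914/\$2205). Mixes enter as
expected costs — the model is cohort-level, not patient-level.

**QALYs.** Grade utilities 0.89 / 0.797 / 0.65 / 0.588 / 0.363 / 0.092 /
0; each month contributes occupancy-weighted utility / 12. Costs and
QALYs are discounted at 2 %/year as `(1.02)^(−(m − 1)/12)` for a month-`m`
cashflow.

The ICER is Δcost/ΔQALY, with verdicts for the degenerate quadrants:
*Dominant* (cheaper, more effective), *Dominated*, *Undefined*
(ΔQALY = 0). All results are occupancy-fraction arithmetic, so they are
invariant to nominal cohort size.

## Sensitivity and scenario analysis

`run_dsa()` sweeps the published one-way ranges (efficacy via explicit
initial distributions 45.0/51.1/3.9 and 53.8/42.2/3.9 — the latter sums
to 99.9 % and is renormalised; splits pushed to all-best / all-worst
grade; utilization ±10 %; rehabilitation fees ×0.5/×2; long-term-care
fees ×0.5/×2; 1 vs 9 units/day), refitting nothing: the calibration is
frozen from the base configuration. Fee-type parameters obey exact
multiplicative identities on the healthcare-perspective ICER (×0.5, ×2,
×1/4.3, ×9/4.3). The published upper units/day ICER is *less* than base
× 9/4.3, which is inconsistent with uncapped linear fee arithmetic; no
undocumented cap is invented here, so that absolute value is not a test
target.

`run_psa()` draws, independently per iteration: risk ratio
Normal(1.31, 0.05) — read as mean/SD, since an SD of √0.05 would dwarf
the published CI — clipped so the derived initial mRS0-2 stays feasible;
units/day Normal(4.3, 1.0), redrawn if ≤ 0; utilities Gamma(shape, rate)
per grade (the pairs reproduce the point utilities, e.g. 61.0/68.5 =
0.890); care-level costs Gamma(shape, rate) as printed (these pairs do
*not* reproduce the printed cost means under either gamma
parameterisation — they are used as printed, with a config override).
The draws table records raw gamma draws; the unit cap on utilities is
applied where a draw is used and the capped count reported — capping
inside the recorded draws would visibly bias the sample means that the
tests check. "Per patient" draws are read as per-iteration draws: a
cohort model has no per-patient state. Everything is seeded and
bit-reproducible.

`run_scenarios()` re-runs at 0 % and 4 % discounting and at a 120-month
horizon. (A published scenario table shows the 0 % ΔQALY *below* the 4 %
one — the monotonically impossible direction; the suite asserts the
monotone one.)

## Synthetic inputs and what passing tests mean

The package ships no third-party data. Two inputs are stand-ins, clearly
labelled synthetic:

* `inst/extdata/life_table_synthetic.csv` — a Gompertz life table,
  `q(age) = 0.018 · exp(0.095 · (age − 75))` over ages 75–95, matching
  `gen_life_table()`. The parameters are typical of old-age mortality in
  a high-longevity population (mortality doubling roughly every 7 years);
  any real national life table can be dropped in via
  `paths$life_table`.
* `inst/extdata/calibration_targets_synthetic.csv` — landmark survival
  0.83 / 0.74 / 0.66 / 0.58 / 0.50 at months 12–60 (including the 3.9 %
  dead at entry) with independence-among-survivors rising from 0.44 to
  0.52. These were fixed once from the long-term course typical of
  elderly stroke cohorts: substantial first-year excess mortality
  concentrated in the disabled state, about half the cohort dead at five
  years, and a survivor population slowly enriched for the independent.
  The published model calibrated to targets in its supplementary
  material (derived from a long-term stroke cohort study) that are not
  reproduced in the main text.

Consequently the *structural* results — fee arithmetic, the \$836.63
medical increment, conservation, monotonicity, exact scaling identities,
parameter recovery, dominance from the combined perspective, 100 % PSA
acceptability — are fully determined and tested, while *absolute*
base-case values depend on the stand-in targets: this build yields a
healthcare-perspective ICER of \$4613/QALY (published: \$6339), ΔQALY
0.181 (published: 0.132) and combined-perspective dominance with Δtotal
−\$3794 (published: −\$1524). Users with access to the original
calibration targets can supply them via `paths$calibration_targets` and
should expect the published values. The synthetic generator also cannot
emulate patient-level heterogeneity (it is a cohort forward model), so
passing tests say nothing about microsimulation behaviour — out of scope
by design.

## Problem sizes and numerical choices

The shipped analyses are deliberately small: 57–117 cycle traces,
1000-point calibration grids with Nelder-Mead refinement (about 1.5 s),
1000 PSA iterations (about 1.5 s), 20-truth recovery studies (about
40 s). Ties in the ICER quadrants are resolved by verdict before
division; `ΔQALY = 0` returns a verdict, never an exception or an
infinity. Degenerate inputs (empty landmark lists, non-stochastic rows,
risk ratios driving a death probability above 1) fail fast with the
offending cycle or key named.

## Worked example

```{r example, eval = FALSE}
cfg <- freeze_calibration(base_case_config())
run_cea(cfg)
run_scenarios(cfg)[, c("scenario", "delta_qaly", "icer_healthcare")]
psa <- run_psa(cfg, n_iterations = 1000)
psa$summary$pct_below_wtp_combined
```

## Known limitations

* Absolute base-case costs/QALYs inherit the synthetic calibration
  targets (above); only quantities pinned by the main-text inputs are
  reproduced exactly.
* The care-cost gamma pairs are internally inconsistent in the source
  table and used as printed.
* Hospital-perspective costs (weekend staffing), opportunity and societal
  costs, and convalescent-stage medical costs are out of scope, as in the
  published analysis.
* The efficacy evidence is observational; the model propagates it, it
  cannot de-bias it.
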