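---
title: "A Markov microsimulation of CTP-based occlusion screening in acute stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov microsimulation of CTP-based occlusion screening in acute stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpcea)
```

## The decision problem

Patients presenting within six hours of acute ischemic stroke (AIS) symptom
onset are screened for a large vessel occlusion (LVO) — an occlusion of the
internal carotid artery (ICA/ICA-terminus) or of the M1 or proximal M2
segment of the middle cerebral artery — because such occlusions can be
treated with endovascular thrombectomy (EVT), which substantially improves
functional outcome. Adding CT perfusion (CTP) to the standard imaging
protocol of non-contrast CT (NCCT) plus CT angiography (CTA) raises the
sensitivity of LVO detection, so fewer treatable occlusions are missed; but
every suspected-stroke patient then receives an extra scan, and only about
one in 4.3 to 8.3 of them (the *number needed to image*, NNI) turns out to
harbour an EVT-eligible LVO.

`ctpcea` quantifies this trade-off from a healthcare-payer perspective. Per
LVO patient it reports, over a 5- or 10-year horizon:

* **ΔQALYs** — difference in discounted quality-adjusted life years between
  an NCCT+CTA+CTP strategy and an NCCT+CTA strategy,
* **ΔCosts** — difference in discounted costs (screening, acute treatment,
  mRS-dependent follow-up care),
* **NMB** — net monetary benefit, `NMB = WTP × ΔQALY − ΔCosts`, at a
  willingness to pay (WTP) of €80,000 per QALY. A positive NMB means the CTP
  strategy is cost-effective at that WTP.

## Model structure

The model couples a short-term (90-day) outcome model with a yearly
long-term Markov microsimulation.

**Cohort.** A synthetic cohort of 701 EVT-treated LVO patients emulates the
descriptive statistics of a Dutch multicentre registry population:
occlusion strata ICA/M1/M2 weighted 168/367/166, per-stratum 90-day
modified Rankin Scale (mRS) distributions taken from the published
per-stratum counts, age from a truncated normal (mean 71.5, sd 13.5,
bounds 18–100) with per-stratum shifts −2/0/+1 years so the overall median
is ≈72 with IQR ≈62–81, 55.6% male, 67.3% receiving intravenous
thrombolysis (IVT). Age and mRS are drawn independently within stratum, and
sex/IVT independently overall, because only marginal summaries of the joint
distribution are available. The generator does **not** emulate NIHSS,
ASPECTS, collateral scores, perfusion volumes or workflow times: the
economic model never consumes them. Passing tests on this cohort therefore
demonstrate correctness of the simulation machinery under these marginal
distributions, not fidelity to any real joint patient distribution.

**Counterfactual control arm.** In the NCCT+CTA arm a patient's LVO is
missed with the occlusion-specific *sensitivity difference* (defaults: 8%
ICA, 16% M1/M2; configurable, varied ±8 percentage points in scenarios).
Missed patients lose the EVT benefit: their observed (treated) 90-day mRS
is mapped to a counterfactual no-EVT mRS by dividing the cumulative odds of
every mRS cutpoint by the common EVT odds ratio (default 1.67, 95% CI
1.21–2.30), the proportional-odds summary under which EVT trials report
their effect. The realisation is *rank-preserving*: each patient carries a
latent uniform deviate, re-anchored within the treated CDF cell of the
observed state, and the counterfactual state is the inverse CDF of the
shifted distribution at that point. This coupling (rather than an
independent redraw) reduces Monte-Carlo noise and guarantees that removing
EVT can never improve an individual's outcome; marginally it reproduces the
shifted distribution exactly, which the tests verify. Differences in
specificity between the strategies, and futile angio-suite transfers, are
deliberately out of scope.

**Long-term simulation.** From 90 days onward, each patient's mRS evolves in
yearly cycles. In each cycle, in order:

1. *death trial*: annual probability `min(1, q(age, sex, year) × HR_mort(mRS))`
   with mortality hazard ratios 1.54/2.17/3.18/4.55/6.55 for mRS 0–1/2/3/4/5;
2. *recurrence trial* (survivors): `min(1, baseline(years since stroke) ×
   HR_rec(age band, mRS))`;
3. *redistribution* after a recurrence: the new state is drawn from the
   stratum's no-EVT (odds-shifted) 90-day distribution truncated to
   `[current state, 6]` and renormalised — a pure "deterioration" reading in
   which a recurrent stroke can only worsen function, and a draw of mRS 6 is
   a fatal recurrence.

Placing the death trial first prevents double-counting fatal recurrences.
States are recorded end-of-cycle without half-cycle correction; ages and
the calendar year advance one year per cycle (simulations start in 2022).
Death is absorbing, and because redistribution is truncated below the
current state, trajectories are monotone non-decreasing in mRS — both are
tested invariants. Both arms are simulated on **common random numbers**
(one uniform stream per patient and trial type), so paired differences
isolate the arm effect and identical arms yield identical trajectories.

**Economics.** Costs and QALYs accrue per accrual year `t = 1..horizon`,
keyed to the mRS state entering the year (year 1 is keyed to the 90-day
state for the whole year; part-year weighting is not attempted). Yearly
costs use the first-year / second-year / third-year-onward cost rows; the
year-2+ lookup uses the current-year state, a simplification of the
18-month-state keying of the source cost study. The mRS-6 cost row is
charged once, in the year death occurs (patients dead at 90 days get the
year-1 mRS-6 cost), and nothing accrues afterwards. QALYs use mRS-level
utilities 0.94/0.80/0.68/0.39/0.24/0 (mRS 0–1 merged, as in all mRS-keyed
tables). QALYs are discounted at 4%/year and costs at 1.5%/year with the
first year undiscounted, consistent with a 2022 start. Acute costs — CTP
€251.40 (the printed composite value is used as-is), EVT €9924.50, IVT
€950.82 — carry a 42% hospital overhead; the overhead is read as applying
to all acute items including CTP, with a configuration switch
(`overhead_applies_to_ctp`) to exempt CTP. Screening adds
`(NNI − 1) × cost_CTP × overhead` per LVO patient in the CTP arm, the index
patient's own CTP sitting in the acute cost, so total CTP spend per LVO is
`NNI × cost_CTP` either way. Acute and screening costs fall in year 0 and
are not discounted. IVT is assumed given in both arms, and the NCCT+CTA
cost is identical across arms, so both difference out. All reference-year
(2015) costs are inflated once at load to the 2022 price level using the
inflation series; simulation-era costs are then kept in constant 2022 euros
(inflation beyond the start year enters only through the discounting
convention).

## Fixture stand-ins

Three inputs of the original evaluation are not published and are shipped as
clearly labelled synthetic stand-ins, each overridable by CSV:

* **Life table** (`make_life_table()`): Gompertz–Makeham
  `q(age) = min(1, a + b·c^age)` with `a = 2·10⁻⁴`, `c = 1.1` and `b`
  calibrated per sex by root finding so that life expectancy at age 72 is
  14 years (women) and 12 years (men). The table is year-invariant; a real
  national table with a `year` column is honoured by nearest-year lookup.
* **Recurrence baseline** (`default_recurrence_baseline()`): 4%/year in the
  first year after the index stroke, declining to 2% by year 5, constant
  thereafter.
* **Recurrence hazard ratios** (`default_hr_recurrence()`): stepped 1.0→2.0
  over mRS 0–1→5 with mild age-band multipliers (1.1/1.0/0.95/0.9 for
  <65/65–74/75–84/85+), clamped to [1, 2].

The mortality-HR source reports log-normal uncertainty without printing
intervals; PSA draws use a stand-in 95% CI of HR/1.3–HR×1.3, and the
recurrence-HR table gets a single log-normal multiplier with σ = 0.15.

## Baseline, tornado, PSA

**Baseline** (`run_baseline()`) evaluates the model at the parameter means.
Two variance-reduction choices make it effectively deterministic: the
missed/not-missed selection is taken in expectation (each patient's control
outcome is the sensitivity-difference-weighted mixture of the missed and
not-missed branches — exact, because the not-missed branch shares its event
stream with the CTP arm and cancels), and residual event noise is averaged
over 20–30 common-random-number stream replications. The run is
bit-reproducible from its seed.

**Tornado** (`one_way_sensitivity()`) varies each scalar input to 0.9× and
1.1× with identical seeds and ranks parameters by the NMB swing. NNI,
sensitivity differences and the EVT effect are excluded here — they get the
dedicated scenario grid.

**PSA** (`run_psa()`, 1000 replicates by default) bootstraps whole patients
with replacement (stratum labels preserved), draws one parameter set per
replicate — log-normal odds/hazard ratios, gamma costs, beta utilities,
fixed prices/NNI/rates — rebuilds the arms with Bernoulli missed-selection,
simulates on common random numbers and records cohort-mean ΔCosts, ΔQALYs
and NMB. Parameter draws are replicate-level (one set per bootstrap cohort),
standard PSA practice. The per-replicate seed schedule is derived once from
the master seed, so across scenario-grid cells that differ only in NNI the
health gain is *bit-identical* — NNI enters the model exclusively through
the deterministic screening cost, and the grid reproduces that structure
exactly. ICER-plane exports give per-stratum replicate means without the
screening cost (which is not attributable to a stratum) and pooled means
with it.

## Numerical choices

* CI→σ conversions use 1.959964 (not 1.96); immaterial, fixed for
  reproducibility.
* Beta method-of-moments specifications with infeasible variance
  (`sd² ≥ mean(1−mean)`) or boundary means degrade to a point mass (with a
  warning in the infeasible case); the mRS-6 utility is pinned to 0.
* Degenerate odds-shift cutpoints (cumulative probability 0 or 1) map to
  themselves; the shifted CDF is re-monotonised against floating-point
  wobble; shifted distributions sum to 1 within 1e-12.
* Ages outside the life table clamp to its bounds with a warning;
  redistribution with no mass at or above the current state leaves the
  state unchanged.
* Problem sizes: test-suite simulations use cohorts of 150–700 patients and
  PSAs of 15–250 replicates; the analysis scripts and the acceptance script
  use the full 701-patient cohort with 1000-replicate PSAs. These sizes were
  chosen so each analysis completes in seconds to a couple of minutes on a
  single core.

## What the model does and does not reproduce

With the default (study-condition) inputs the model yields a baseline
5-year health gain of ΔQALY ≈ 0.049 per LVO patient and a 10-year PSA
median of ≈ 0.073, with the health gain scaling linearly in the sensitivity
difference and invariant to NNI — the qualitative and quantitative pattern
expected of CTP-based screening benefits.

On the cost side the model is structurally conservative. Under the
proportional-odds counterfactual, withdrawing the EVT effect moves roughly
ten percentage points of probability mass into mRS 6. Death is cheap in the
mRS-keyed cost tables (≈€21k once, then ≈€0.4k/year) while severe
disability is expensive (mRS 4–5: €31k–€55k/year), so the extra deaths in
the control arm largely offset its extra severely-disabled survivors, and
the net follow-up-care saving attributable to detecting an occlusion stays
small relative to the CTP screening spend and the additional EVT
procedures. Consequently ΔCosts stays positive (≈ +€6k per LVO patient)
and the NMB near or below zero at a WTP of €80,000/QALY. A counterfactual
in which missed patients survive as often as treated ones but in worse
functional states — as randomized EVT trials, whose arms had near-equal
90-day mortality, suggest — would make the CTP strategy cost-saving; the
common-odds-ratio mechanism cannot represent that survival-preserving
functional shift. This structural sensitivity of the cost conclusion to
the counterfactual mechanism (and to the stand-in life/recurrence tables)
is the model's principal known limitation; the health-gain conclusions are
robust to it.

Other limitations: no modelling of false positives or contrast/radiation
side effects; healthcare-payer perspective only (no indirect costs); no
value-of-information analysis; utilities and costs are taken as given
parameters, not estimated from individual data.

## Reproducing the analyses

```{r, eval = FALSE}
cohort <- synthesize_cohort(701, seed = 2022)
params <- load_parameters()           # defaults; YAML overrides accepted
params$horizon_years <- 5L

run_baseline(cohort, params, seed = 2022, n_streams = 30)
one_way_sensitivity(cohort, params, seed = 2022)
params$horizon_years <- 10L
run_psa(cohort, params, n_reps = 1000, seed = 2022)
scenario_grid(cohort, params, n_reps = 250, seed = 2022)
```

The numbered scripts under `analysis/` run these steps end-to-end and write
their tables under `results/`; `scripts/acceptance.R` recomputes the
headline quantities from scratch and writes them as JSON.
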