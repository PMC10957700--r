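# ctpcea

Model-based health-economic evaluation of adding CT perfusion (CTP) to a
standard acute-stroke imaging protocol of non-contrast CT (NCCT) plus CT
angiography (CTA) for detecting endovascular-treatment (EVT) eligible large
vessel occlusions (LVO). The package is aimed at health-economists and
stroke researchers who want a transparent, fully testable patient-level
Markov microsimulation of this screening decision.

## The model in brief

A synthetic cohort of 701 EVT-treated LVO patients (occlusion strata
ICA/M1/M2, per-stratum 90-day modified Rankin Scale distributions, median
age 72) is compared against a counterfactual NCCT+CTA arm in which each
patient's occlusion is missed with an occlusion-specific probability (the
*sensitivity difference* of CTP-based detection: 8% ICA, 16% M1/M2).
Missed patients lose the EVT benefit: their 90-day mRS distribution is
shifted by dividing the cumulative odds at every mRS cutpoint by the common
EVT odds ratio (1.67, 95% CI 1.21–2.30), realised per patient through a
rank-preserving latent-uniform coupling. Yearly mRS trajectories are then
simulated to a 5- or 10-year horizon with life-table mortality inflated by
mRS-specific hazard ratios and recurrent-stroke deterioration. Discounted
costs (1.5%/year) and QALYs (4%/year) accrue from mRS-keyed yearly cost and
utility tables; the CTP arm additionally pays the screening cost of the
number needed to image (NNI, 4.3–8.3) per detected LVO. The primary outcome
is the net monetary benefit at a willingness to pay (WTP) of €80,000/QALY,

    NMB = WTP × (QALY_CTP − QALY_control) − (Costs_CTP − Costs_control),

reported with one-way (tornado), probabilistic (1000 bootstrap replicates
with log-normal/gamma/beta parameter draws) and scenario-grid sensitivity
analyses. See `vignettes/ctp-cost-effectiveness.Rmd` for the full model
description, assumptions and limitations.

## Worked example

```r
library(ctpcea)

cohort <- synthesize_cohort(701, seed = 2022)   # synthetic study cohort
params <- load_parameters()                     # published defaults
params$horizon_years <- 5L

bl <- run_baseline(cohort, params, seed = 2022, n_streams = 30)
```

which prints, via `analysis/02_baseline.R`:

```
Baseline (5-year horizon, NNI 8.3, WTP 80,000 EUR/QALY):
  delta QALYs per LVO patient: 0.0491
  delta costs per LVO patient: EUR 6009
  net monetary benefit:        EUR -2081
```

Read: per LVO patient, CTP-based screening buys ≈0.049 discounted QALYs
over five years (the health gain of not missing treatable occlusions) at
≈€6.0k extra cost (CTP screening of ~8.3 suspected-stroke patients per
detected LVO, plus the additional thrombectomies, minus follow-up-care
savings). At €80,000/QALY the monetised health gain (≈€3.9k) does not cover
the extra cost, giving a negative NMB — under this model's
proportional-odds counterfactual the cost conclusion is structurally
conservative (see the vignette's limitations section). The 10-year PSA
(`analysis/04_psa.R`) yields a median health gain of 0.073 QALYs
(IQR 0.052–0.094) per LVO patient.

The numbered scripts under `analysis/` run the whole workflow — cohort
synthesis, baseline, tornado, PSA, scenario grid — and write their tables
under `results/`.

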