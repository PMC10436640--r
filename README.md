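# ipceval

Evaluation toolkit for internet-based pharmaceutical care (IPC) in
hypertension. The package rebuilds, as tested R code, the analysis
pipeline used to judge a one-year pharmacist-led WeChat intervention in
96 young and middle-aged hypertensive patients:

* **Questionnaire scoring** — a 25-item adherence/lifestyle scale
  (Likert 1–5) with reverse-coded items Q1, Q6–Q13 flipped as
  `x -> 6 - x`; blood-pressure control defined as SBP ≤ 120 mmHg and
  DBP ≤ 90 mmHg (home nighttime measurement); completion acceptable
  strictly under 10 minutes.
* **Reliability screen** — NIPALS PCA per questionnaire with a 99%
  Hotelling T² control ellipse,
  `T²_i = Σ_a t²_ia / s²_a` against
  `A(N−1)(N+1)/(N(N−A)) · F₀.₉₉(A, N−A)`,
  a 10% acceptance rule, and per-variable contribution plots for
  flagged patients.
* **OPLS-DA before/after comparison** — one predictive + `n_ortho`
  orthogonal components, S-plot coordinates
  `(cov(t_p, x_k), corr(t_p, x_k))`, and signed VIP
  (`VIP_k = √K·|w_k|` carrying the sign of the S-plot covariance) with
  selection at |signed VIP| ≥ 0.5 plus an S-plot reliability gate.
* **Markov cohort cost-effectiveness** — three states (poorly
  controlled, well controlled, dead), annual cycles over a 28-year
  horizon, deaths first within each cycle, poor→well at the arm's
  control probability (0.7188 IPC / 0.11 none), well→poor relapse at
  the population hypertension incidence 27.5%, poor-state mortality
  `P_MH = P_IR · P_CDMR · P_MACD = 0.2750 × 0.455 × (1.8279/2.815) =
  0.0812`, well-state mortality 7.18‰. Life years, QALYs, cumulative
  cost, cost-effectiveness ratio against a ¥57,700 willingness-to-pay
  threshold, and one-way sensitivity analysis.
* **Synthetic cohorts** — a moment-calibrated latent-trait generator
  reproducing the study structure (sex-stratified baselines, a 13/7
  mmHg BP drop from month 3, a 15-point score gain at 12 months carried
  by 10 designated items, one dropout), so every stage is testable
  without patient data.

## Worked example

```r
library(ipceval)

cfg    <- cohort_config(seed = 42)          # study-scale defaults
cohort <- generate_cohort(cfg)
scored <- score_cohort(cohort)

screen_questionnaire(scored, timepoint = 2)
#> Hotelling T2 screen: 2/96 outside the 99% ellipse (2.08%) -> PASS (<= 10%)
#> flagged: P032, P090

compare_timepoints(scored, 1, 4)
#> OPLS-DA, questionnaire 1 vs 4, 95 paired patients, R2Y = 0.862
#> selected variables (signed VIP):
#>   Q1   +1.55
#>   Q6   +1.54
#>   ...
#>   sbp  -0.80
#>   dbp  -0.79
```

The screen says the simulated second questionnaire is reliable (2.08%
of patients outside the 99% ellipse, under the 10% allowance), and the
before/after comparison recovers exactly the ten items whose
improvement the generator injected — positive because scores rose — and
blood pressure with a negative sign because it fell.

```r
tr_ipc  <- run_markov_cohort(markov_params("ipc"))
tr_none <- run_markov_cohort(markov_params("none"))
life_years(tr_ipc); life_years(tr_none)
#> [1] 18.63661
#> [1] 13.22741
incremental_qaly(tr_ipc, tr_none)
#> [1] 5.4092
cer(470.37, 5.40)
#> [1] 87.11
one_way_sensitivity(markov_params("ipc"))
#>   scenario  value deaths life_years     cost
#> 1    -0.10 0.6188     57   18.10346 500.2303
#> 2    +0.00 0.7188     55   18.63661 466.9581
#> 3    +0.10 0.8188     52   19.09747 437.7698
```

Survival is 18.64 years with the intervention versus 13.23 without
(5.41 incremental QALYs at unit utilities), the cost-effectiveness
ratio is about ¥87 per QALY — far below the ¥57,700 threshold — and
moving the control probability by ±10 percentage points moves 28-cycle
deaths between 57 and 52 of 96 patients.

See `vignettes/ipc-evaluation.Rmd` for the model details, the
calibration of the cycle-accounting convention, and known limitations.

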