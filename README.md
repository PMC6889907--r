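# pamsim

Policy simulation of physical-activity interventions on the socioeconomic
gradient in children's internalizing mental-health problems.

Children from the poorest households are roughly three times as likely as
those from the richest to show internalizing problems (top-decile SDQ
emotional + peer score) by late childhood. Physical activity is weakly
protective and is a lever policy can actually pull — so how much of the
prevalence, and of the income gradient, could realistic activity
interventions remove? `pamsim` implements the full pipeline for that
question, for epidemiologists and quantitative policy analysts:

* a **calibrated synthetic-cohort generator** standing in for restricted
  UK birth-cohort data (income quintiles, DAG-consistent confounders,
  accelerometer-style MVPA with a weak *reverse* income gradient, 0–20
  internalizing scores, design weights), plus a Monte-Carlo oracle for the
  true counterfactual effects;
* **marginal structural models**: weighted logistic regression (IRLS) with
  stabilized inverse-probability-of-treatment weights for the income
  exposure and Gaussian density-ratio weights for the continuous mediator,
  winsorized at the 1st/99th percentiles and combined with design weights,
  giving the crude association, the total direct effect (TDE), and the
  controlled direct effect (CDE) of income;
* a **scenario engine**: eligibility predicates × Bernoulli uptake ×
  truncated-normal effectiveness increments, applied to the mediator at
  prediction time with coefficients held at their observed-data estimates,
  singly or combined into a proportionate-universal package;
* inequality summaries from the linear-quintile model — risk ratio
  RR = p̂(q=1)/p̂(q=5) and risk difference RD = p̂(q=1) − p̂(q=5) — with
  percentile-bootstrap confidence intervals.

## The model in brief

With income quintile Q, confounders X, Box–Cox-transformed MVPA M
(λ = 0.34) and internalizing case Y, the CDE analysis weights each child by

    w = trim[ P(Q=q) / P(Q=q|X) ] × trim[ f(M|Q) / f(M|Q,X) ] × design weight

and fits the weighted logistic MSM  logit P(Y=1) = β₀ + β₁·q + β₂·M.
Intervention scenarios replace M by M(m + Δ), Δ ≥ 0 drawn per child from
the scenario's eligibility/uptake/effectiveness model, and re-predict.

## Worked example

```r
library(pamsim)

cfg    <- default_config()                 # calibrated DGP, n = 100,000
cohort <- generate_cohort(cfg, seed = 1)

crude <- estimate_crude(cohort)            # design weights only
tde   <- estimate_tde(cohort)              # + exposure IPTW (baseline confounders)
cde   <- estimate_cde(cohort)              # + full weights, mediator in model
render_table(list(crude = crude, tde = tde, cde = cde))
```

```
 model prevalence_pct   rr rd_pct who_attainment_pct n_effective
 crude           11.0 3.34   12.7               50.9       96066
   tde           10.8 2.84   10.9               50.9       84074
   cde           10.6 2.23    8.3               50.9       74962
```

Reading: 11.0% of children have internalizing problems; the crude
extreme-quintile risk ratio of 3.34 (risk difference 12.7 points)
attenuates to 2.23 (8.3 points) once confounding is removed and observed
activity is accounted for — confounders explain about a third of the
inequality, activity very little. Applying the intervention scenarios:

```r
ws  <- build_weights(cohort, "cde")
sc1 <- apply_scenario(cohort, default_scenarios()$scenario1, seed = 1,
                      weight_set = ws)     # universal +30 min/day, full uptake
sc1$effects$attainment_who                 # 0.956 — WHO-target attainment
sc1$effects$overall_prevalence             # 0.097 — down from 0.106
```

Even this hypothetical scenario only trims ~1 point of prevalence and
leaves relative inequality unchanged; the realistic scenarios (break-time,
active transport at 77% uptake, targeted and indicated programmes) move
nothing appreciably — the core policy finding. The numbered scripts under
`analysis/` (`01_simulate.R` … `05_report.R`) run this narrative end to
end and write their tables under `results/`.

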