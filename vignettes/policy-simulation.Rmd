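---
title: "Simulating physical-activity policy effects on child mental-health inequalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating physical-activity policy effects on child mental-health inequalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamsim)
```

## The question and the causal set-up

Children from poorer households report substantially more internalizing
mental-health problems (anxiety- and depression-like symptoms measured by
the parent-reported SDQ emotional and peer subscales, summed to a 0–20
score and dichotomized at the top decile, a cut-off of 8). Physical
activity is a candidate policy lever: it is weakly protective, and it can
be raised by school- and community-level interventions. `pamsim`
implements the full chain of reasoning needed to ask *"would raising
children's moderate-to-vigorous physical activity (MVPA) reduce the
prevalence and the income gradient of internalizing problems?"*:

1. estimate the income → internalizing effect with confounding removed by
   weighting rather than covariate adjustment (a marginal structural
   model, MSM);
2. hold the mediator (MVPA) accounted for, yielding the *controlled
   direct effect* (CDE) of income;
3. re-predict outcome probabilities after manipulating the mediator the
   way a real intervention would (eligibility × uptake × effectiveness),
   holding the fitted coefficients fixed.

Income enters as equivalized household-income quintiles (1 = lowest).
Baseline confounders are maternal age at first live birth and ethnicity;
intermediate confounders, measured at the mediator's sweep, are perceived
neighbourhood safety, maternal psychological distress (Kessler-6-like,
0–24), child overweight, longstanding illness, and conduct/hyperactivity
problems (the latter guards against reverse causation from externalizing
behaviour to activity).

## Estimators

**Weights.** The exposure model is a multinomial logistic regression of
quintile on confounders (no proportional-odds restriction is imposed).
Stabilized inverse-probability-of-treatment weights are
$w_i = P(Q = q_i)/P(Q = q_i \mid X_i)$. For the CDE the continuous
mediator gets stabilized density-ratio weights
$f(m_i \mid q_i) / f(m_i \mid q_i, X_i)$, both densities Gaussian on the
Box–Cox scale with means from weighted least squares and a single
homoscedastic residual scale per model. Every weight component is
winsorized at its 1st/99th percentiles (linear-interpolation percentiles;
clamping, not dropping, so the sample size is retained) and multiplied by
the design weight.

**Outcome models.** Weighted logistic regressions fitted by IRLS
(convergence: maximum absolute score < 1e-8 or relative log-likelihood
change < 1e-10; rank-deficient designs and separation are reported). The
inequality summaries use income quintile as a *linear* term: the risk
ratio RR = $\hat p(q{=}1)/\hat p(q{=}5)$ and risk difference
RD = $\hat p(q{=}1)-\hat p(q{=}5)$, where $\hat p(k)$ averages per-child
fitted probabilities with the quintile code set to $k$ and all other
terms (including the mediator) at their per-child values, weighted by the
analysis weights. Any affine recoding of the quintile axis leaves RR and
RD at the extreme codes unchanged.

**Scenarios.** A scenario is an eligibility predicate over cohort fields,
an uptake probability (optionally income-differential), and a
truncated-normal (at zero) effectiveness increment in minutes/day,
optionally stratum-specific (e.g. active-transport: mean 4, SD 2 for
children with no active commute leg; mean 2, SD 1 for one active leg).
Scenario predictions reuse the coefficients fitted on observed data and
change only the mediator values at prediction time. Combined packages sum
independently sampled increments per child. Confidence intervals, where
requested, come from a percentile bootstrap over children (design weights
travel with the child).

## The synthetic generator and its calibration

Real cohort data of this kind are access-restricted, so the package ships
a generator whose defaults reproduce the published marginals of the UK
birth-cohort accelerometer sample it emulates. The generator is
first-class, tested code: all estimator validation runs against it and
against a Monte-Carlo oracle (`true_effects()`) that evaluates the
counterfactual quintile contrast directly from the generating outcome
model.

Choices that were genuinely open, and how they were fixed:

* **MVPA distribution.** Only medians and two tail shares are published,
  so the distributional family is a modelling choice: MVPA is the inverse
  Box–Cox ($\lambda = 0.34$) of a Gaussian, truncated at zero — matching
  the transform used in the regression models and guaranteeing
  non-negativity. Per-quintile locations and the common scale were solved
  so that the *population* share meeting the 60-min WHO target is exactly
  0.510, the share below 30 min exactly 0.044 (so a universal +30-min
  intervention yields 95.6% attainment), and the lowest/highest-quintile
  medians exactly 62 and 59 min.
* **A rounding incompatibility.** An overall median of exactly 61 min
  together with 51% at ≥60 min would require only 1% of children between
  60 and 61 min; any smooth distribution at this scale places ≈1.9% of
  mass there. The printed values are rounded, and the two constraints
  cannot hold simultaneously. The shares were pinned exactly and the
  population median lands at 60.55 min, inside the 1-minute reporting
  precision of the published median.
* **Outcome calibration.** The logistic outcome model has per-quintile
  direct effects (linear in the quintile code), confounder effects, and a
  small negative mediator coefficient per transformed MVPA unit. The
  intercept, the direct-effect scale and the confounder-effect scale were
  solved — against a deterministic population computation on a fixed
  mega-sample, plus replicate estimator runs — so that the *estimated*
  quantities land on the published ones: prevalence 0.1095, crude
  linear-quintile RR 3.25 (RD 12.4 points), and weighted CDE RR 2.2. The
  published trio (11%, RR 3.3, RD 12) is itself mutually inconsistent at
  the ≈2σ level under a linear-logistic profile with equal quintile
  shares, so the calibration minimizes joint deviation rather than
  matching each number exactly.
* **Positivity.** Confounder–income gradients were chosen mild enough
  that stabilized exposure weights stay within roughly [0.2, 10]. With
  steeper gradients the 1%/99% winsorizing step clamps highly informative
  weights and visibly re-admits confounding; with the shipped defaults
  the winsorized CDE estimator sits only ≈+0.08 log-RR above the
  untrimmed one.
* **Internalizing score.** Case status is drawn from the logistic model;
  the integer score is then drawn from 8–19 for cases and 0–7 for
  non-cases through a monotone map of the case probability, so the
  top-decile cut-off of 8 reproduces itself exactly.
* **Design weights** are i.i.d. lognormal with mean 1 (no cluster or
  stratum structure): they exercise the weighted-analysis path without
  emulating a survey design.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: longitudinal attrition and non-MCAR
missingness (an MCAR switch exists purely to exercise complete-case
handling), accelerometer wear-time artefacts, survey strata/clusters, and
any effect modification by sex or income (the generating models are
modification-free by construction).

## Numerical choices

* Box–Cox at zero minutes: exact zeros are transformed as 0.5 min (below
  the resolution of a daily accelerometer summary) so the transform is
  finite for every λ.
* Quintile assignment from raw values uses weighted cumulative shares
  with ties collapsed to the lower stratum.
* Winsorizing uses type-7 (linear-interpolation) percentiles. Clamping is
  idempotent up to the interpolation granularity of the recomputed bound
  (about 1% of the local gap between order statistics).
* Truncated-normal increments are drawn by inverse-CDF sampling; their
  mean exceeds the nominal mean by the standard truncation correction
  $\sigma\phi(\mu/\sigma)/\Phi(\mu/\sigma)$ (for the active-transport
  stratum with mean 4, SD 2 the simulated mean is 4.11 min).
* All randomness descends from one global seed through named substreams
  (`derive_seed(seed, "cohort")`, `"uptake:<scenario>"`, …), so each stage
  is reproducible in isolation and identical configuration + seed gives
  byte-identical outputs.
* Problem sizes: the calibration checks run on a single cohort of
  100,000 children; estimator-oracle comparisons use Monte-Carlo samples
  of 400,000 and replicate cohorts of 40,000 for the estimator's own MC
  standard error. Unit tests use 1,500–50,000 children per case.

## Known limitations

* The winsorized (1st/99th percentile) weighted estimator is not exactly
  unbiased for the oracle CDE functional: trimming re-admits a small,
  known-direction residual of confounding (≈+0.08 log-RR at the shipped
  defaults). Identification is therefore verified on the untrimmed
  weights, and the trimmed production estimator is checked for direction
  and magnitude of the offset. This mirrors the behaviour of the
  published procedure, which also trims.
* The model-based (fixed-weight) standard error of the inequality
  summaries understates the estimator's true sampling variability because
  the weights are estimated; bootstrap or replicate-based errors should
  be used where that matters.
* Scenario parameters not carried by the published description
  (scenario 2's SD and uptake, scenario 4's uptake and effect size,
  scenario 5's effect size) ship as placeholders flagged
  `unverified = TRUE`; conclusions about those scenarios test the
  machinery, not the evidence base.
* Weight construction details of the original analysis (its appendix is
  not part of the available text) are reconstructed as the standard CDE
  construction: multinomial exposure model, Gaussian density-ratio
  mediator weights on the transformed scale.
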