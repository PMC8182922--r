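---
title: "Correcting prevalence estimates for loss to follow-up: methods and design"
author: "followupbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting prevalence estimates for loss to follow-up: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(followupbias)
```

## The problem

Population-based cohorts of children born very preterm (< 32 weeks of
gestation) routinely lose 25–50% of families by the 2-year follow-up, and
attrition is not random: response is strongly patterned by maternal and
social factors (young maternal age, multiparity, foreign birth, not
breastfeeding at discharge, residence in deprived areas), while the
perinatal factors that most strongly predict neurodevelopmental impairment
are only weakly related to response. If, in addition, parents of impaired
children respond less *given* everything observed at baseline, the data are
missing not at random (MNAR) and no correction based on observed covariates
can fully remove the bias.

`followupbias` implements the full analysis pipeline for this situation:
describing attrition, correcting the prevalence estimate of a binary
outcome under a missing-at-random (MAR) assumption by multiple imputation
(MI) and by inverse probability of follow-up weighting (IPW), and probing
the MAR assumption with a delta (log-odds offset) sensitivity analysis.
Because individual-level cohort data of this kind are not publicly
distributable, the package ships a synthetic cohort generator that
reproduces the statistical structure these analyses assume, and every
estimator is validated by parameter recovery against the generator's known
truth.

## Outcome derivation

The binary outcome is moderate-to-severe neurodevelopmental impairment at
2 years of corrected age, a composite of:

* **gross motor impairment** — any of three parent-reported flags (unable
  to walk without assistance, unable to sit without support, unable to
  hold the head up), and/or
* **non-verbal cognitive (NVC) impairment** — a PARCA-R NVC score below 22,
  where the score is the sum of 34 binary parent-report items and the
  threshold corresponds to the 2.5th percentile of a term-born reference
  population. The inequality is strict: a score of 21 is impaired, 22 is
  not.

Two derivation rules are deliberate design choices rather than published
prescriptions, and are therefore worth restating:

* **No partial scoring.** If any of the 34 items is missing the score — and
  hence the NVC flag — is missing. There is no accepted pro-rating rule for
  partially completed PARCA-R item sets, and outcome missingness among
  responders is handled by the imputation machinery downstream, which is
  exactly what it is for.
* **Three-valued composite.** The "and/or" composite uses Kleene logic: the
  composite is 1 as soon as any observed component is 1 (even if other
  components are missing), 0 only when all components are observed and 0,
  and missing otherwise. This classifies every child whose composite is
  determinable from partial data; the test suite verifies the rule against
  a possible-worlds enumeration over all 81 three-valued inputs and checks
  monotonicity.

## Multiple imputation engine

`run_mice()` is a chained-equations engine with posterior-draw conditional
models, following the convention of treating each incomplete variable with
a Bayesian-motivated draw rather than a deterministic prediction:

1. fit the maximum-likelihood regression of the variable on its predictors
   over the originally observed rows (binary logit for 0/1 variables,
   multinomial logit for categorical variables, Bayesian linear regression
   with predictive mean matching for continuous compatibility);
2. draw a coefficient vector from the asymptotic normal approximation of
   the posterior (mean = MLE, covariance = inverse observed information);
3. form the linear predictor for the rows to impute — adding the delta
   offset if the variable is the outcome — and draw imputed values from
   the implied distribution.

Defaults and the reasoning behind them:

* `m = 100` imputations (the analysis standard for this design); the test
  suite and examples use 10–20, which is ample for point-estimate recovery.
* `n_iterations = 15` chained cycles. In this data structure the chains
  converge much faster than that: covariate missingness is shallow
  (0.2–4% per variable), so the outcome's imputation model is fit on rows
  whose predictors are essentially complete from the first cycle. The
  heavy simulation suites in the tests therefore run 3–5 cycles after
  confirming flat chain-mean traces; `chain_means` diagnostics are
  returned so users can check the same on their data.
* **Visit order** is increasing fraction of missingness, the standard
  choice, so poorly informed draws propagate least.
* **Predictors**: by default every modeled variable is predicted by region,
  the follow-up indicator, all baseline covariates and the outcome (minus
  itself). Including the outcome in covariate imputation models, and
  imputing the outcome for non-responders and for responders with missing
  questionnaires alike, are both essential for an unbiased MAR correction.
* **The outcome is imputed directly as a binary variable**, not item by
  item: the estimand is the composite's prevalence, and item-level
  imputation would require a 37-dimensional model the data cannot support.
* **Degenerate fits**: a variable with a single observed class is imputed
  constant (with a warning); separated logistic fits fall back to a
  ridge-stabilized fit (penalty 1e-4) and are flagged.
* **Numerics**: binary models use a direct Fisher-scoring MLE and the
  multinomial a Newton–Raphson MLE, both warm-started across cycles and
  imputations because the engine refits them thousands of times; the test
  suite asserts agreement with `stats::glm` and `nnet::multinom`. Linear
  predictors are clamped at ±30 before exponentiation; aliased dummy
  columns are dropped by a rank-revealing QR.

### Seeding and coupling

Every (imputation, cycle, variable) step draws from its own deterministic
substream derived from the master seed. This gives three properties the
analysis relies on: reruns are bit-identical; the m chains are independent;
and two runs that differ only in the delta offset share every random draw
whose inputs they share. The last property couples the cells of the
sensitivity grid so that the estimated prevalence is (empirically)
monotone in delta — differences between scenarios are attributable to
delta, not Monte-Carlo noise — and makes the delta = 0 cell literally
bit-identical to the MAR run.

## Delta sensitivity analysis

The delta method modifies the MAR imputation model by adding a fixed
offset delta to the outcome's linear predictor before drawing imputations:
delta is the assumed difference in outcome log-odds between children with
missing and with observed outcomes, conditional on the model's covariates;
`exp(delta)` is the corresponding odds multiplier. The default grid spans
delta from −0.2 to 0.4 (odds multipliers ≈ 0.8 to 1.5), i.e. up to the
scenario where children lost to follow-up have 50% higher odds of
impairment than observed ones. The offset applies to *all* imputed outcome
values — the sensitivity parameter does not distinguish the two routes to
a missing outcome (non-response vs missing questionnaires), because it is
defined as a single contrast between missing and observed.

A useful identity justifies anchoring: conditional on covariates, the
log-odds ratio between impairment and non-response is symmetric, so if the
generator makes impaired children respond with a log-odds deficit of
`delta_true`, the imputation offset `delta = delta_true` is exactly the
correction that restores the MAR analysis — which is what the
parameter-recovery suite verifies.

## Inverse probability weighting

The IPW path mirrors the usual two-stage design: candidate predictors of
follow-up are screened by a region-adjusted bivariate logistic association
test at a deliberately liberal p ≤ 0.2 (so variables associated with
follow-up only conditionally on others can enter), a multivariable
logistic response model is fit on rows complete for the retained
predictors, and responders are weighted by the reciprocal of their fitted
response probability. Two design choices deserve flagging:

* **Responders with missing outcomes are excluded from the weighted
  mean.** Their weight addresses loss to follow-up, not item missingness;
  including them is impossible (no outcome) and re-weighting for item
  missingness would be a second, different model. How such children entered
  the original analyses of this design is not documented; this choice is
  explicit here.
* **The sandwich variance treats weights as fixed.** Ignoring the
  estimation uncertainty of the weights is the common, typically
  conservative default; a bootstrap variance is available via
  `ipw_config(variance_method = "bootstrap")`.

The imputed-predictor variant (`ipw_on_imputed()`) multiply-imputes
*covariates only* — the outcome is excluded and stays as observed — then
runs screen–fit–weight per completed dataset and pools by Rubin's rules,
recovering the rows the complete-case response model drops.

## Pooling

`rubin_pool()` combines per-imputation proportions on the logit scale
(delta-method variances), with total variance `T = W + (1 + 1/m) B` and
Barnard–Rubin degrees of freedom, then back-transforms — keeping intervals
inside [0, 1]. The crude estimator uses the matching logit-scale Wald
interval so that crude and corrected intervals are comparable; boundary
estimates receive a 0.5/(n+1) continuity adjustment with a warning.
Pooling on the raw proportion scale is available for comparison
(`scale = "raw"`). Display rounding is 1 decimal, half-up, applied only at
render time.

## The synthetic cohort generator

`default_epice_like_config()` encodes the study conditions the estimators
are validated under:

* **Margins.** Two regions (PT 34.7%, UK 65.3%); eleven baseline
  covariates with the marginal frequencies of a European very-preterm
  cohort (maternal age in three classes, parity, foreign birth, previous
  cesarean, PPROM, breastfeeding at discharge, sex, gestational-age group,
  low 5-minute Apgar, severe neonatal morbidity, and an area-deprivation
  quintile).
* **Effects.** The covariate log-odds for response and for impairment are
  the log-odds ratios computed from the observed two-way tables of such a
  cohort, so the generator reproduces the qualitative pattern that matters
  here: response is driven by social covariates (deprivation quintile 5 vs
  1: log-OR ≈ −1.2; maternal age ≤ 24: ≈ −0.9) and barely by neonatal
  morbidity (≈ +0.05), while impairment is driven by perinatal factors
  (gestation 23–25 weeks: ≈ +1.5; severe morbidity: ≈ +1.2; male sex:
  ≈ +0.7) and not by deprivation (0). The model intercepts are calibrated
  by exact enumeration of the covariate joint distribution so the marginal
  response rate is 54.2% and the latent prevalence 18.4%.
* **Attrition mechanism.** With `delta_true = 0`, follow-up is MAR given
  covariates; `delta_true = d` subtracts `d × latent_impaired` from the
  response linear predictor, making impaired children less likely to
  respond — the MNAR mechanism the delta analysis is designed to detect
  (`delta_true = 0.4` ≈ "impaired children 1.5× less likely to be
  followed up").
* **Items.** Impaired children draw an NVC score uniformly on 10..21
  (weight 0.8) or a motor flag with a high NVC score (weight 0.2);
  unimpaired children draw scores on 24..34 with motor flags clear. Each
  item then flips independently with `item_error_rate = 0.001`. The rate
  is deliberately small: the generator's purpose is attribution of
  estimator bias to *missingness*, so the instrument is designed to be
  nearly measurement-faithful (the derived prevalence sits ~0.2–0.3
  percentage points above the latent one, from rare motor false
  positives). Real parent-report instruments have larger and structured
  measurement error; passing recovery tests here says nothing about
  outcome misclassification in real data.
* **Missingness.** Responders' questionnaires go missing jointly with
  probability 0.111; per-covariate MCAR rates (0–4.2%, largest for the
  deprivation index) are calibrated so ~14.5% of rows have at least one
  missing covariate. Covariate missingness being MCAR is a simplification
  — the generator emulates the reported *amounts*, not a mechanism that
  was never reported.

What the generator does **not** emulate: the real joint (interacting)
covariate distribution, gestational-age-specific survival, multiple-birth
clustering (children are independent; whether non-response operated at the
family level is unknown, so the generator does not model it), non-response
mechanisms outside the single log-odds shift family, and structured
measurement error. Estimator properties demonstrated on these cohorts
transfer to real data only insofar as those simplifications are harmless.

## Problem sizes used in validation

The packaged validation suites run at deliberately scaled-down sizes
chosen to leave Monte-Carlo error well below the tolerances being
asserted: parameter recovery uses 50 replicate cohorts of n = 3000 with
m = 20 imputations and 3 cycles (mean-bias tolerances of ±1.5 percentage
points, against per-seed estimator SDs of ~0.9 pp); the delta grid is
checked for monotonicity on 3 seeds at n = 2000, m = 10; null calibration
of the screening machinery uses 200 replicates at n = 1800. The
acceptance script re-runs the same pipeline at n = 3000 with 10 seeds per
mechanism.

## Known limitations

* The normal approximation behind the posterior draws is poor in tiny
  strata or for near-separated models; the ridge fallback keeps the engine
  running but slightly attenuates extreme coefficients.
* The delta analysis explores a single constant-offset pattern-mixture
  family; selection-model (Heckman-type) sensitivity analyses and richer
  pattern mixtures are out of scope.
* IPW assumes the response model is correctly specified over the retained
  predictors; the Horvitz–Thompson weight-sum diagnostic (reported in
  `weight_set` diagnostics) is the first thing to inspect when in doubt.
* p-values from the association scan are bivariate (region-adjusted only),
  matching the descriptive use they serve; they are not adjusted for
  multiplicity, and the screening threshold is intentionally not a
  significance test.
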