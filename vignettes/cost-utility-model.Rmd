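---
title: "A decision-tree + Markov cost-utility model for revascularisation strategies in cardiogenic shock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree + Markov cost-utility model for revascularisation strategies in cardiogenic shock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shockcea)
library(dplyr)
```

## The decision problem

Patients with acute myocardial infarction, multivessel coronary disease and
cardiogenic shock can be revascularised in two ways: culprit-lesion-only
PCI with staged treatment of the remaining lesions if indicated (CO-PCI),
or immediate PCI of every significant stenosis (MV-PCI). The randomised
evidence shows lower 30-day mortality under CO-PCI but more repeat
revascularisation and heart-failure re-admissions during the first year.
Whether the early survival gain is worth the extra downstream resource use
is an economic question, and the answer depends strongly on the time
horizon: most of the QALY benefit of saving a life in month one accrues
years later.

`shockcea` implements the full evaluation pipeline for this comparison
from a German societal perspective: patient-level costing and estimation,
a one-year decision tree, a lifelong monthly-cycle Markov cohort model,
and the decision metrics (ICER, net monetary benefit, CEAC,
cost-effectiveness plane), with probabilistic sensitivity and subgroup
analyses. Because no patient-level dataset from the trial is public, the
package also ships a calibrated synthetic-data generator so that every
stage is testable end to end.

## Model structure

**Year one: decision tree.** Each arm first faces 30-day mortality (43.3%
CO-PCI vs. 51.5% MV-PCI in the calibration). Survivors land in exactly one
of five mutually exclusive one-year states, assigned with strict priority:

1. death (any cause),
2. renal failure — renal replacement therapy *and* alive at one year,
3. heart failure — re-hospitalisation for heart failure,
4. MACE — myocardial infarction, stroke or revascularisation (urgent or
   staged),
5. alive and stable (A&S) — the residual.

A dialysed patient who dies is in the death state; the priority rule makes
the states a partition, which the classifier (`classify_states()`)
enforces and the tests check as a property.

CO-PCI probabilities are not estimated independently: the MV-PCI arm
provides baseline probabilities and per-endpoint relative risks carry the
treatment effect, with A&S as the residual after the four event states.
This mirrors how the treatment effect is transported to subgroups later.

**Beyond year one: Markov cohort model.** One-year survivors enter a
five-state monthly-cycle chain (A&S, renal failure, heart failure, MACE,
death). Death is absorbing. Only A&S patients can develop renal or heart
failure (chronic states cannot revert); every living state can suffer a
MACE; a MACE patient who neither dies nor suffers a recurrence returns to
A&S after one cycle — recurrence is modelled as staying in MACE for the
next cycle before the reset applies. Long-term renal-failure incidence is
zero by default because no new renal replacement was observed after the
acute phase; the rate is exposed as a configuration override.

Transitions happen at the beginning of each cycle and payoffs accrue in
the post-transition state for 1/12 year, discounted at 3% per year with
factor $(1+r)^{-c/12}$ at cycle $c$. We deliberately do **not** apply a
half-cycle correction: the model's stated timing convention is
begin-of-cycle transitions, and fidelity to that convention beats generic
practice here. The engine terminates at the horizon (age 100 by default —
"lifelong" left unspecified is operationalised as run-to-extinction) or
when living mass falls below $10^{-9}$.

**Mortality extrapolation.** Within-trial survival models predict only the
first Markov cycle's death probability; thereafter the monthly probability
scales proportionally to age-specific annual mortality from a life table,
$p(c) = \min\{1,\; p_1 \, q(\text{age}_c)/q(\text{age}_1)\}$, with age
advancing one year every 12 cycles. This prevents a constant-hazard
extrapolation from producing implausible long-term survival. The package
ships a synthetic Gompertz–Makeham life table
(`synthetic_life_table()`) calibrated to round western-European
magnitudes; any table with columns `age`, `annual_death_prob` can be
substituted.

## Parameter estimation

* **Tree probabilities** (`estimate_tree_probabilities()`) are raw
  frequencies; relative risks are ratios of proportions with the standard
  log-scale standard error $\sqrt{1/a - 1/n_1 + 1/b - 1/n_2}$ (needed for
  the PSA; the published tables print only p-values). Zero event counts
  get a 0.5 continuity correction with a warning.
* **Long-term hazards** (`fit_survival()`) are parametric fits —
  exponential, Weibull, Gompertz, log-logistic, log-normal — by maximum
  likelihood via `flexsurv`, with left truncation at day 30 and censoring
  at day 365. Only the 30-day-to-1-year window is used because the acute
  30-day hazard spike would otherwise contaminate the extrapolation. The
  family minimising AIC wins; ties break towards fewer parameters; BIC is
  reported alongside. Covariates are arm, age group, sex and diabetes,
  plus the health state for the death model. The state of a patient at
  risk is their one-year state if they survive and the state they held at
  death otherwise — the estimation window needs a state for decedents and
  this is the least-assumption choice.
* **Utilities and follow-up costs** (`fit_panel_model()`) come from
  linear mixed models with a patient random intercept (`lme4`), health
  state as the variable of interest (reference A&S, death fixed at 0) and
  the baseline covariates as controls. The utility panel uses the 30-day,
  6- and 12-month EQ5D waves; a follow-up-wave fixed effect absorbs the
  recovery trend (utilities rise from ~0.74 at 30 days to ~0.84 at one
  year), which the published coefficient table folds into the state and
  covariate terms. The cost panel regresses the 6- and 12-month
  hospitalisation + emergency-room cost per wave; the Markov cycle cost is
  the per-state prediction divided by 6 (the recall window is six
  months). For the long-term MACE utility the MACE state is re-defined to
  urgent revascularisation / MI / stroke only: first-year staged
  revascularisations are protocol-driven, not prognostic of future
  events.

State values enter the model as *marginal* predictions — each patient is
predicted under every state and the predictions averaged — so a subgroup's
utilities are automatically "re-centred to the subgroup average" with
shared state offsets, exactly the subgroup adaptation rule.

## The synthetic trial generator

`sim_config()` / `simulate_cohort()` emulate a two-arm cohort of 343
patients per arm with the published structure: Bernoulli 30-day mortality
per arm; a categorical one-year endpoint for survivors (integer-consistent
with the published percentages: e.g. 87/195 MACE among CO-PCI survivors);
event days inside (30, 365] from configurable parametric families
(exponential by default, so that recovery tests know the truth); EQ5D
panels as patient random intercept + state/wave/covariate shifts +
truncated-normal noise on the German value-set range $[-0.205, 1]$; and
gamma resource-use quantities with coefficient of variation 1.5, matching
the heavy right skew of critical-care costs.

Choices worth making explicit:

* **Ages** are uniform within group bounds (30–49, 50–75, 76–95): only
  group membership is published, but the Markov stage needs numeric ages.
* **Decedents carry their pre-death morbidity.** Patients dying between
  30 days and one year receive a pre-death state drawn from their arm's
  non-death endpoint mix, with the triggering event placed before the
  death day. Without this, all late deaths would sit in the A&S stratum
  and the state-conditional death hazard would differ sharply between arms
  — an artefact; the trial's survival analysis found near-identical
  conditional hazards, and the generator reproduces that pattern by
  construction.
* **Cost calibration is exact in expectation.** Per-category mean euro
  amounts follow the published resource-use table; structural components
  (annual dialysis for renal survivors at one year, friction-cost
  productivity) follow their rules; and the gamma category means are then
  rescaled by one factor per arm so the analytic expected total
  (`expected_total_cost()`) equals €25,371 / €24,531 exactly. Follow-up
  hospital use is concentrated in the sicker states via renormalised
  weights, chosen so the implied cost-model coefficients sit near the
  published ones (heart failure ≈ +€1,900 per six-month window).
* **Within-patient utility correlation** is not published; the
  between/within standard deviations (0.12 / 0.08) are free parameters of
  the generator, and recovery tests use tighter values so truncation bias
  cannot mask a real estimation error.
* What the generator does **not** emulate: treatment crossovers,
  per-lesion angiographic detail, informative missingness (blanking is
  completely at random among the structurally present fields),
  correlation between resource categories, and count-valued device use
  (gamma draws are continuous). Passing tests therefore demonstrate that
  the estimators and the engine are correct under the assumed data
  model, not that the assumed model captures every feature of real trial
  data.

## Costing rules

`patient_total_cost()` multiplies quantities by unit costs with the
trial-specific exceptions: 30-day self-reported inpatient days are
excluded (they double-count the eCRF index stay); angiography is a DRG
tariff prorated by fluoroscopy minutes; renal replacement adds a full
dialysis-year cost only for patients alive at day 365; medications cost
days-at-standard-dose times a daily price; productivity losses follow the
friction-cost method with a 60-working-day (8-hour) friction period —
non-workers cost zero, leaving work for over 60 days or dying before 65
costs the full period, returns to unpaid work or reduced hours cost 30 and
10 days. The daily value of a working day is configurable (default €280
for an 8-hour day); the friction rule fixes hours, not the wage.

Missing hospitalisation and emergency-room quantities are imputed
deterministically: zero when the patient died before the follow-up window
opened, otherwise the mean of observed values in the same survival stratum
at that follow-up (alive at the wave vs. died during the window), with a
logged fallback to the overall mean for empty strata. The published
outlier footnote is not in the main text, so the default screen — drop
values above the 99.9th percentile of the positive per-category
distribution, logged and reversible — is deliberately conservative, and
the pipeline applies it only to the self-reported follow-up fields whose
blanked values re-enter the imputation.

## Probabilistic sensitivity analysis

`run_psa()` propagates independent parameter draws through the model:
Beta from event counts for absolute risks, moment-matched Beta for
utilities, shifted Beta on $[-0.5, 0.5]$ for incremental (state-offset)
utilities, gamma for costs, lognormal for relative risks. Two details are
our own:

* All distributions are **mean-matched to the point estimates** —
  lognormal draws use $\mu = \log \hat\theta - \sigma^2/2$ — so the
  simulation is centred on the deterministic base case and the
  zero-uncertainty degeneracy check is exact.
* Long-term hazard uncertainty enters as lognormal multipliers on the
  three fitted transition hazards with scale equal to the fitted
  intercept's standard error, capped at 0.7 on the log scale. The cap
  stabilises near-uninformative event models (a handful of heart-failure
  events can produce an intercept SE of 50 on the log scale, which would
  make half the draws clinically absurd). The multipliers are shared
  between arms, so between-arm long-term uncertainty is carried by the
  relative risks only; this understates the extrapolation uncertainty
  relative to sampling each arm's hazard independently, and is the main
  reason the package's acceptability curves are tighter than the
  published ones.
* The lifelong model inside the PSA is evaluated at the modal covariate
  cell with the cohort-average entry age (the deterministic base case
  aggregates over the full age × sex × diabetes mixture). One cell keeps
  10,000 draws inside a few minutes on one CPU; the within-trial
  quantities are unaffected.

Conditional endpoint draws keep A&S as the residual after the four
sampled event probabilities, renormalising when the events alone exceed 1
— the published account names marginal families only, and the residual
construction is the only way to keep the vector a distribution draw by
draw.

## Calibrated base case and problem sizes

`calibrated_base_case()` runs the whole two-stage model from the published
tables alone: tree counts, utility means and model coefficients, per-arm
cost totals, and closed-form exponential long-term hazards whose
30-day-to-1-year cumulative risks equal the published conditional
probabilities (state-specific long-term hazards are not published, so the
calibration uses state-neutral mortality). On the synthetic life table it
reproduces the published ordering and magnitudes — ICERs of roughly €9.6k
per composite case avoided (published 9,010), €13.7k/QALY within trial
(published 14,600) and €6.8k/QALY lifelong (published 7,010) — and a
lifelong incremental QALY more than three times the within-trial
increment, the qualitative signature of the analysis (about five times in
the published cohort, whose life-table and age profile differ from our
synthetic stand-ins).

The test suite sizes simulations to keep the full run inside a half hour
on one CPU while leaving Monte-Carlo margins honest: law-of-large-numbers
checks at $10^5$ patients per arm, the engine-versus-micro-simulation
oracle at $10^6$ walkers, survival family selection over 50 seeds at
$n = 5000$, PSA convergence at 10,000 draws. These sizes are choices, not
limits of the method.

## Known limitations

* The life table, unit-cost table and medication aggregation are
  synthetic stand-ins with realistic magnitudes, so absolute lifelong
  costs and QALYs are not comparable to national-tariff results; the
  incremental comparisons, which the evaluation is about, are.
* The Markov stage applies the MACE cycle cost to the MACE cycle itself
  (the published cost model estimates a MACE coefficient, so we use it);
  if MACE costs were purely transitional this would double-count one
  cycle's difference — at €90 per cycle the effect is negligible.
* Utilities are modelled on the linear scale and clipped to the valid
  range; with means near 0.8 and the published dispersions the clipping
  is rare, but extreme configurations can bias cohort means slightly
  below their nominal values.
* The PSA treats parameters as independent apart from the residual A&S
  construction; correlations induced by joint estimation (e.g. between
  state offsets) are ignored, as in most published cost-effectiveness
  PSAs.
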