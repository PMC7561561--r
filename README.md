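# shockcea

Cost-utility modelling of revascularisation strategies in acute
myocardial infarction complicated by cardiogenic shock: culprit-lesion-only
PCI (CO-PCI, with staged revascularisation if indicated) versus immediate
multivessel PCI (MV-PCI), from a German societal perspective.

CO-PCI lowers 30-day mortality but leads to more repeat revascularisation
and heart-failure re-admissions over the first year. Whether that
trade-off is worth paying for depends on the horizon: the package
implements the three standard views side by side —

* a **30-day cost-effectiveness analysis** (cost per case of the composite
  death / renal-failure outcome avoided),
* a **within-trial cost-utility analysis** (cost per QALY over one year,
  from a decision tree over five mutually exclusive health states:
  death, renal failure, heart failure, MACE, alive-and-stable), and
* a **lifelong cost-utility analysis** that chains the tree into a
  monthly-cycle Markov cohort model with parametric survival
  extrapolation and life-table proportional mortality,
  $p(c) = \min\{1, p_1\, q(\mathrm{age}_c)/q(\mathrm{age}_1)\}$.

Decision metrics are the ICER with dominance labels, the net monetary
benefit $\lambda E - C$, cost-effectiveness acceptability curves and the
cost-effectiveness plane, with Monte-Carlo probabilistic sensitivity
analysis (Beta / gamma / lognormal parameter draws) and protocol subgroup
analyses (age groups, sex, diabetes).

No patient-level data from the trial are public, so the package ships

* the published arm-level summary tables (`ref_tree_table()`,
  `ref_utility_table()`, `ref_cost_table()`, …) used for calibration and
  closed-form arithmetic checks, and
* a calibrated synthetic patient-level generator
  (`sim_config()` / `simulate_cohort()`) so the full pipeline —
  health-state classification, friction-cost costing with
  conditional-mean imputation, decision-tree probabilities and relative
  risks, AIC-selected parametric survival fits (exponential, Weibull,
  Gompertz, log-logistic, log-normal; left-truncated at day 30),
  random-intercept utility and cost panel models, the two-stage engine
  and the PSA — is testable end to end.

## Worked example

The deterministic base case built purely from the published summary
tables:

```r
library(shockcea)
bc <- calibrated_base_case()
bc$icers
#> # A tibble: 3 × 5
#>   analysis     delta_cost delta_effect   icer label
#>   <chr>             <dbl>        <dbl>  <dbl> <chr>
#> 1 cea_30d            840        0.0874  9606. icer
#> 2 cua_1y             840        0.0615 13650. icer
#> 3 cua_lifelong      1360.       0.200   6801. icer
```

Read: CO-PCI costs €840 more per patient over the first year and avoids
the 30-day composite outcome in 8.7% more patients (≈ €9,600 per case
avoided); it buys 0.0615 QALYs within the trial year (≈ €13,700/QALY);
extending to the lifelong horizon more than triples the QALY gain (0.200)
while costs grow much less, so the ICER falls to ≈ €6,800/QALY — the
core message that a short horizon understates the value of the early
survival benefit.

The same machinery runs on patient-level data. On a freshly simulated
trial-sized cohort (343 patients per arm; estimates are noisy at this
size, exactly as the real trial's are):

```r
cohort <- simulate_cohort(sim_config(seed = 42))
pl <- cua_pipeline(cohort)
pl
#> Cost-utility pipeline (686 patients)
#> Survival families: death=gompertz, heart failure=gompertz, MACE=loglogistic
#> # A tibble: 3 × 5
#>   analysis     delta_cost delta_effect  icer label
#>   <chr>             <dbl>        <dbl> <dbl> <chr>
#> 1 cea_30d          -1954.        0.169   NA  dominates
#> 2 cua_1y           -1954.        0.127   NA  dominates
#> 3 cua_lifelong       689.        1.39   497. icer
```

Uncertainty and subgroups:

```r
psa  <- run_psa(psa_spec_from_pipeline(pl), psa_model_from_pipeline(pl),
                n_draws = 10000, seed = 1)
inc  <- psa_increments(psa, effect = "qaly")
plot_ceac(build_ceac(inc))   # P(CO-PCI cost-effective) vs. value of a QALY
plot_cep(inc, lambda = 30000)
subgroup_analysis(pl)        # age / sex / diabetes, lifelong CUA each
```

`tidy()` / `glance()` methods expose every fitted object (tree
parameters, survival fits, panel models, PSA results) as tibbles.

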