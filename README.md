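# ipwrmst

Confounder-standardized **restricted mean survival time (RMST)** analysis
for observational time-to-event data with **competing risks**, with
**inverse-probability-of-exposure weighting** and percentile-bootstrap
inference.

## The problem

Epidemiological cohorts routinely compare time-to-event outcomes between
exposure groups that differ in baseline characteristics, while a
competing event can preclude the event of interest — e.g. comparing time
to treatment initiation between patient groups when death or
loss-to-care makes initiation unobservable. Hazard ratios require
proportional hazards and are hard to read as absolute effects. The RMST

$$A(t^*) = E[\min(T, t^*)] = \int_0^{t^*} S(t)\,dt$$

is the expected event-free time through horizon $t^*$, read directly in
time units. This package estimates it from weighted step curves:

* **Stabilized IPW weights** $\hat W_i = \hat P(X=x_i)/\hat P(X=x_i\mid Z_i)$
  from a logistic exposure model with spline-coded continuous
  confounders, standardizing both exposure groups to the full-sample
  covariate distribution (`fit_stabilized_weights()`).
* **Weighted Kaplan-Meier** survival and **weighted cumulative-incidence
  functions** (Aalen-Johansen type)
  $\hat F_j(t)=\sum_{t_k\le t}\hat S^{\hat W}(t_{k-1})\,d_j^{\hat W}(t_k)/n^{\hat W}(t_k)$,
  in product-limit (default, exactly additive:
  $\hat F_j+\hat F_{J\ne j}+\hat S=1$) or exponential-cumulative-hazard
  form (`weighted_km()`, `weighted_cif()`).
* **Exact Riemann-sum integration** of step curves to the horizon
  (`integrate_step_curve()`, `rmst_survival()`).
* The **event-free restricted mean** for competing risks,
  $A_{J=j}(t^*) - L_{J\ne j}(t^*) = \int(1-\hat F_j) - \int \hat F_{J\ne j}$
  — time spent free of *all* events (`event_free_rmst()`).
* **Percentile-bootstrap CIs** (2.5th/97.5th percentiles) that refit the
  weight model inside every replicate (`bootstrap_estimate()`).
* Comparator estimands: pointwise risk-ratio, risk-difference,
  cause-specific and subdistribution hazard-ratio curves, and a weighted
  Cox fit for a binary exposure (`hazard_ratio_curve()`,
  `weighted_cox_binary()`).
* A **synthetic cohort generator** with known counterfactual truth for
  validation (`sim_config()`, `generate_cohort()`,
  `true_marginal_contrast()`), emulating an HIV clinical cohort
  (confounded binary exposure, treatment initiation vs a composite
  death/loss-to-clinic competing event, 5-year horizon).

All user-facing functions take a data frame first and return tibbles, so
analyses compose with the pipe; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

```r
library(ipwrmst)

cohort <- generate_cohort(sim_config(n = 3000, seed = 1))
covs <- c("age", "cd4", "lrna", "male", "prior_aids", "prior_art")

wm <- fit_stabilized_weights(cohort, covs)
glance(wm)
#> # A tibble: 1 × 7
#>       n stabilized marginal_p_exposed weight_min weight_mean weight_max   ess
#>   <int> <lgl>                   <dbl>      <dbl>       <dbl>      <dbl> <dbl>
#> 1  3000 TRUE                    0.388      0.566        1.00       1.85 2908.

est <- event_free_rmst(cohort, horizon = 5, weights = wm)
rmst_contrast(est)
#> # A tibble: 1 × 6
#>   estimand        group horizon estimate conf_low conf_high
#>   <chr>           <chr>   <dbl>    <dbl>    <dbl>     <dbl>
#> 1 event_free_rmst 1 - 0       5    0.298       NA        NA
```

The contrast says exposed subjects spend 0.30 more years (out of 5) free
of both the event of interest and the competing event — here a direct
consequence of the generator's exposure effects (the exposed initiate
the event of interest more slowly, log-HR log 0.75). Attach a bootstrap
CI, refitting weights per replicate:

```r
bt <- bootstrap_estimate(
  cohort,
  function(d) {
    m <- fit_stabilized_weights(d, covs)
    c(diff = rmst_contrast(event_free_rmst(d, 5, m))$estimate)
  },
  n_boot = 1000, seed = 2)
tidy(bt)
#> # A tibble: 1 × 4
#>   term  estimate conf_low conf_high
#>   <chr>    <dbl>    <dbl>     <dbl>
#> 1 diff     0.298    0.185     0.405
```

`run_analysis()` chains the whole workflow (complete-case filtering,
weights, curves, RMST table with CIs, comparator curves) with optional
era stratification, and `inst/cli/ipwrmst.R` exposes `simulate` and
`run-all` subcommands for shell use.

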