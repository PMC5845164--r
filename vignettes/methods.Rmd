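---
title: "Weighted restricted mean survival time with competing risks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted restricted mean survival time with competing risks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ipwrmst)
```

## The estimand

For a time-to-event outcome $T$ and a horizon $t^*$ no later than the end
of follow-up, the restricted mean survival time (RMST)

$$A(t^*) = E[\min(T, t^*)] = \int_0^{t^*} S(t)\,dt$$

is the expected event-free time accumulated over $[0, t^*]$. Unlike a
hazard ratio it requires no proportional-hazards assumption, remains
meaningful when group survival curves diverge and later converge, and is
read directly in time units ("0.19 years of survival lost over five
years"). Contrasts between exposure groups are taken as differences
$A_1(t^*) - A_0(t^*)$ or ratios.

When a competing event can preclude the event of interest (in the
motivating HIV application: death or loss-to-clinic precludes observing
antiretroviral-therapy initiation), the quantity of applied interest is
the restricted mean time spent free of *all* events,

$$A_{J=j}(t^*) - L_{J\neq j}(t^*)
  = \int_0^{t^*} \bigl(1 - F_j(t)\bigr)\,dt
  - \int_0^{t^*} F_{J\neq j}(t)\,dt,$$

where $F_j$ is the cumulative incidence function (CIF) of the event of
interest and $F_{J\neq j}$ the CIF of the composite competing event.
`event_free_rmst()` implements this; algebraically it equals
$\int_0^{t^*}(1 - F_j - F_{J\neq j})$, the integral of the all-cause
event-free survival curve, and the package verifies that identity to
machine precision in its test suite.

## Estimation

**Weights.** Confounding is handled by stabilized
inverse-probability-of-exposure weights
$\hat W_i = \hat P(X = x_i)/\hat P(X = x_i \mid Z_i)$: the denominator is
a logistic regression of exposure on baseline covariates, the numerator
the marginal exposure proportion. Weighting each exposure group by
$\hat W$ standardizes both groups to the covariate distribution of the
whole sample, so weighted curves are directly contrastable. Continuous
covariates enter the denominator model through natural cubic splines
(`splines::ns`), 4 df by default with interior knots at equally spaced
quantiles; the reference this package follows specifies cubic splines
without fixing knots or df, so the df is a tunable argument
(`spline_df`). Stabilized weights average 1 by construction; an
unstabilized option (`stabilize = FALSE`) is provided.

Fitted exposure probabilities are clipped to $[10^{-6}, 1-10^{-6}]$
purely as overflow protection; probabilities outside $[0.01, 0.99]$
trigger a warning (a positivity alarm, not an error), and probabilities
at numerical 0/1 — the signature of separation, where the logistic MLE
diverges — are an error naming the offending terms. Weight truncation
(`truncate_weights()`, order-statistic percentiles) is available as a
robustness utility but is never applied by default.

**Curves.** `risk_table()` aggregates a cohort into distinct event times
$t_k \le t^*$ with weighted at-risk totals $n^{\hat W}(t_k)$ and weighted
event counts $d_j^{\hat W}(t_k)$ per cause; weighted counts are sums of
subject weights, never rounded, and a subject censored at $t_k$ is still
at risk for events at $t_k$ (events precede censorings at ties — the
standard survival convention, adopted because the methodology we follow
is silent on ties). The weighted CIF is the Aalen-Johansen-type sum

$$\hat F_j(t) = \sum_{t_k\le t} \hat S^{\hat W}(t_{k-1})\,
  \frac{d_j^{\hat W}(t_k)}{n^{\hat W}(t_k)},$$

with $\hat S^{\hat W}$ the overall (all-cause) weighted survival curve.
Two forms of $\hat S^{\hat W}$ are implemented:

* `product_limit` (default): $\prod_{t_k \le t}(1 - d/n)$, the weighted
  Kaplan-Meier form. With this form
  $\hat F_j + \hat F_{J\neq j} + \hat S = 1$ holds *exactly* at every
  knot, so the CIFs and the survival curve partition probability — the
  property the event-free estimand relies on.
* `exp_cumhaz`: $\exp\{-\sum_{t_k\le t} d/n\}$, the Breslow-type
  exponential-cumulative-hazard form in which the estimator is sometimes
  printed. Since $e^{-h} > 1-h$ for $h>0$, this curve sits strictly above
  the product-limit curve once events occur and the three-way sum then
  exceeds 1. Both forms are exposed because the printed definition and
  the additivity identity are mutually exact only in the product-limit
  form; the package defaults to the form that makes the identity exact
  and regression-tests the sign of the discrepancy in the other.

**Integration.** All curves are right-continuous step functions, so the
RMST integral is an exact Riemann sum over the steps,
$\sum_k \hat S(t_{k-1})(t_k - t_{k-1})$, with $t^*$ appended as the final
knot. There is no quadrature error and no extrapolation: a horizon beyond
the last observed follow-up time is an error rather than a guess.

**Inference.** Confidence intervals are nonparametric percentile
bootstrap: subjects are resampled with replacement (unrestricted — not
stratified by exposure, matching the source methodology's description),
and the *entire* pipeline, including the weight model, is refit in each
replicate so the interval carries weight-estimation uncertainty. The 95%
interval is the 2.5th/97.5th empirical percentiles (quantile type 7,
linear interpolation; at the reference analysis' 10,000 replicates the
quantile definition is immaterial, but it is fixed for reproducibility).
All replicate resampling indices are drawn up front from the seed, so
results are bit-reproducible and independent of execution order.
Replicates that fail (e.g. separation in a small resample) are dropped
and counted; more than 5% failures aborts with a diagnostic.

## Comparator estimands

For context alongside the RMST contrast, the package computes the
conventional pointwise curves from the same weighted objects: risk ratio
$(1-S_1)/(1-S_0)$ and risk difference $(1-S_1)-(1-S_0)$ from the weighted
survival curves; pointwise all-cause and cause-specific hazard ratios as
ratios of discrete hazards $d/n$; the pointwise subdistribution hazard
ratio from $\Delta\hat F_j(t_k)/(1-\hat F_j(t_k^-))$; and a
single-coefficient weighted Cox model (Breslow ties) for a binary
exposure as the conventional one-number summary. Points where a ratio is
undefined (zero reference risk or hazard, empty risk set) are carried as
`NA`, never interpolated or fabricated. A full subdistribution-hazard
*regression* is deliberately out of scope — only the pointwise curve that
the comparison figures require is computed. Smoothing of these noisy
pointwise curves is considered a plot-layer concern and is not applied to
the exported values.

## The synthetic cohort generator

No public data release exists for the motivating cohort, so validation
rests on simulation with known counterfactual truth. `sim_config()`
declares the full mechanism: covariate marginals, a logistic
exposure-assignment model, independent cause-specific
(piecewise-)exponential latent event times given exposure and covariates,
and administrative plus optional random censoring. Defaults were fixed
once to the shape of the application cohort: n = 3000; age, CD4 count and
log10 viral RNA as continuous covariates (normal / gamma / normal
marginals centred near the published medians); ~65% male, 22% prior
AIDS, 26% prior ART; exposure prevalence ≈ 0.38 (the exposure-model
intercept was calibrated once to this marginal prevalence under the
default covariate distributions and then frozen); an event-of-interest
rate of 0.45/year reduced by exposure (log-HR log 0.75); and a composite
competing event of 0.10/year whose exposure effect (log 1.8) switches on
after year 2 via piecewise-constant rates — deliberately
non-proportional, emulating the late divergence the applied analysis
observed. Administrative censoring sits at 5.5 years so a 5-year horizon
never extrapolates.

Continuous covariates are centred at their distribution means inside all
linear predictors, so intercepts and baseline rates describe the average
subject. `true_marginal_contrast()` evaluates the counterfactual target
by Monte Carlo: one large covariate sample, latent times drawn under both
exposure assignments with common exponential draws (variance reduction),
no censoring. By construction the truth depends only on the outcome
model, never on the assignment model — confounding changes who is
exposed, not what would happen to them.

`confounded_config()` is a deliberately harsher validation scenario in
which severity drives exposure and both hazards in the same direction
(coefficients roughly 2-4× the defaults), producing a crude
restricted-mean contrast biased by ~0.6 years — far beyond sampling noise
at n = 10,000 — which a correctly specified weight model must remove.

What the generator does *not* emulate: calendar-era guideline shifts,
informative censoring, measurement error in covariates, or dependence
between the latent cause-specific times beyond what covariates induce.
Passing recovery tests therefore demonstrates correctness of the
estimators under the stated assumptions (conditional exchangeability,
positivity, correct model specification), not robustness to their
violation in real data.

## Numerical and design choices

* **Tie-break:** events before censorings at the same time.
* **Degenerate inputs:** empty weighted risk sets before the horizon,
  one-level exposure, negative times, unknown event codes, and ratio
  contrasts with a zero reference are explicit errors; all-censored
  cohorts are valid (survival stays at 1).
* **Weighted counts** are real-valued sums of weights; nothing is
  rounded.
* **Era stratification:** `run_analysis()` refits the weight model
  within each stratum (the conservative reading when stratifying a
  standardized analysis), and stratified results equal independent runs
  on the stratum subsets exactly.
* **Missing covariates** are handled by complete-case exclusion before
  any estimation, with the exclusion count reported — matching the
  reference analysis' handling; no imputation is offered.
* **Quantile conventions:** bootstrap percentiles use linear
  interpolation (type 7); weight truncation uses order statistics
  (type 1) so truncation bounds are always observed weights.
* **Problem sizes in the test suite** were chosen to make Monte-Carlo
  error a small fraction of each tolerance: 1000 random cohorts of
  n ≤ 20 against brute-force oracles at 1e-12; n = 100,000 for the
  exponential closed form (tolerance 0.02 years); n = 10,000 for
  confounding recovery (±0.05 years, ≥80% bias reduction); 500 cohorts
  × 200 replicates for bootstrap coverage, judged against the binomial
  (500, 0.95) two-sided 99% band [0.92, 0.975].

## Known limitations

Weights address baseline confounding of a point exposure only: no
time-varying treatments or censoring weights. Inference is bootstrap-only
(no Greenwood/influence-function variances). Left truncation and interval
censoring are unsupported. The event-free estimand inherits the usual
competing-risks caveat that it mixes the event-of-interest and
competing-event processes; its interpretation ("time alive, in care, and
untreated") is application-specific and should be stated alongside any
contrast.

## A worked run

```{r example, eval = FALSE}
cohort <- generate_cohort(sim_config(n = 3000, seed = 1))
wm <- fit_stabilized_weights(
  cohort, c("age", "cd4", "lrna", "male", "prior_aids", "prior_art"))
est <- event_free_rmst(cohort, horizon = 5, weights = wm)
rbind(est, rmst_contrast(est))

bt <- bootstrap_estimate(
  cohort,
  function(d) {
    m <- fit_stabilized_weights(
      d, c("age", "cd4", "lrna", "male", "prior_aids", "prior_art"))
    e <- event_free_rmst(d, 5, m)
    c(diff = rmst_contrast(e)$estimate)
  },
  n_boot = 1000, seed = 2)
tidy(bt)
```
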