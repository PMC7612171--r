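---
title: "G-estimation of structural nested cumulative survival time models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{G-estimation of structural nested cumulative survival time models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sncstm)
```

## The problem

Observational cohorts with repeated exposure and confounder measurements pose
a well-known dilemma for survival analysis. A confounder measured after an
early exposure (lung function after a year of treatment, say) confounds the
*later* exposure, so it must be adjusted for; but it also lies on a causal
pathway from the *earlier* exposure to death, so adjusting for it in a
standard regression deletes part of that exposure's effect and can add
collider-stratification bias on top. The structural nested cumulative
survival time model (SNCSTM) resolves this by parameterizing, for each pair
of visits `k <= l`, the causal effect `psi_k(l)` of the exposure taken at
visit `k` on the hazard inside the window `[s_l, s_{l+1})` *when all later
exposures are removed*. Equivalently, on the survival scale,

$$
\frac{P\{T(\bar A_{k-1}, 0) \ge t \mid \bar A_k, \bar L_k, T \ge s_k\}}
     {P\{T(\bar A_k, 0) \ge t \mid \bar A_k, \bar L_k, T \ge s_k\}}
 = \exp\Big\{\sum_{j=k}^{l-1} A_k\,\psi_k(j)\,(s_{j+1}-s_j)
            + A_k\,\psi_k(l)\,(t-s_l)\Big\},
\qquad s_l \le t < s_{l+1},
$$

where `T(a_bar_k, 0)` is the failure time with exposures after visit `k`
set to zero. On the hazard scale each `psi_k(l)` is an additive hazard
difference (an Aalen-type exposure effect with the confounder part left
unspecified); on the survival scale `exp(psi * time)` is a relative survival
risk. The diagonal `psi_k(k)` is the immediate effect of the visit-`k`
exposure; off-diagonal parameters are controlled direct effects — later
*exposures* are held at zero, but nothing else is held fixed.

Identification rests on three assumptions: *no unmeasured confounders*
(`T(a_bar_{k-1}, 0)` independent of `A_k` given the measured history and
survival to `s_k`), *consistency* (the counterfactual equals the factual
time when the intervened exposures are naturally zero), and correct
specification of a canonical GLM for each exposure given history.

## The estimation procedure

The package fits the model entirely with standard GLM machinery, in five
conceptual steps.

1. **Expansion.** Follow-up is discretised with a step `delta`. Every
   subject at risk at grid time `Q` contributes one *pseudo-individual*
   carrying the survival indicator `I(T >= Q + delta)` over `[Q, Q+delta)`.
   Because consecutive indicators of one subject refer to disjoint risk
   intervals, they are conditionally independent — this is what makes
   pooling over `Q` efficient, unlike stacking highly correlated indicators
   `I(T >= t)` for overlapping `t`.
2. **Step choice.** `choose_delta()` takes the largest step such that no
   sub-interval of any inter-visit window contains more than 10% of that
   window's observed failures (configurable); when a window has too few
   failures for the rule to be satisfiable it falls back to one twentieth
   of the smallest window, the conventional `C/20` in the single-window
   case, with a warning.
3. **Propensity models.** For each `(k, l)` pair the canonical GLM for
   `A_k` (logit for binary, identity for continuous exposures) is fitted on
   the window-`l` rows with the elapsed time `Q - s_k` as an extra
   covariate: under the additive hazard model the exposure law among
   survivors stays in the same canonical family with an intercept drifting
   linearly in time. With effect modifiers, `modifier * (Q - s_k)` columns
   are added; with subject-varying schedules and `l > k`, the intermediate
   interval lengths enter as covariates.
4. **Score equations.** The g-estimator solves, per parameter block,
   `sum_i w_i z_i (y_i exp(-z_i' psi) - 1) = 0` with blip covariate
   `z = -residual * delta_row`, i.e. the score of a gamma log-link GLM with
   no intercept. For lag `d = l - k > 0` the outcome is first *blipped
   down* by `exp{delta_row * sum_{j=k+1}^{l} A_j psi_j(l)}` and the rows are
   weighted by `exp{sum_{j=k+1}^{l} H_j(Q)}` — converting the factual
   at-risk set into the counterfactual one — using only estimates of lag
   `< d`. Estimation therefore proceeds by ascending lag and never
   iterates; this ordering is exactly what makes parameter sharing valid
   only *within* a lag, and `blip_spec()` rejects cross-lag sharing.
5. **Censoring.** Follow-up is truncated at the minimum of failure,
   dropout and the administrative end; rows whose interval outcome is
   unobservable are dropped from the score fits (but still inform the
   propensity fits). Covariate-dependent dropout is handled by a pooled
   discrete-time logistic hazard on the same grid and unstabilized
   cumulative-product inverse-probability weights, applied to both the
   propensity and the score equations, since both average over an at-risk
   population that dropout distorts. Stabilized weights are available
   behind a flag; weights are not truncated.

Standard errors come from a subject-level nonparametric bootstrap
(`bootstrap_sncstm()`) that refits the whole pipeline per replicate. The
grid step is held at the original fit's value across replicates so all of
them share one discretization. Sandwich standard errors are deliberately
not offered: they ignore the propensity estimation step and do not extend
to multiple exposures.

### The score solver

Stock gamma-family software refuses the zero outcomes that survival
indicators produce, although the score equation itself is perfectly well
defined at `y = 0`. `gamma_score_solve()` therefore solves the score
directly: damped Newton (step halving until the score norm decreases, at
most 100 iterations, convergence at max-norm `1e-10`), with a
bracket-and-bisect fallback in one dimension. The score is coordinatewise
monotone for non-negative outcomes, so damped Newton is globally convergent
in practice; agreement with generic gamma IRLS on all-positive outcomes is
part of the test suite, as is agreement with a dense-grid bisection root in
the scalar case.

### Numerical conventions

* Intervals are half-open `[Q, Q + delta_row)`; a failure exactly at
  `Q + delta_row` counts as surviving to it.
* The grid re-anchors at every visit time, so visit times need not be
  multiples of `delta`; a short final sub-interval keeps its true length
  `delta_row < delta`, which replaces `delta` in the blip covariate and the
  blipped outcome of that row.
* A boundary grid point falling exactly on the next visit belongs to the
  later window, where it is that window's anchor.
* The row at the administrative end has no forward interval; it is emitted
  for completeness, flagged outcome-unknown, and contributes to no score
  fit.
* One printed outcome convention in the source procedure would make the
  immediate-effect outcome identically one on the expanded data; the
  package uses `I(T >= Q + delta)` throughout, which is the convention the
  rest of the procedure and the single-visit case imply.
* A death occurring exactly at a visit time contributes no exposure at that
  visit: exposure cannot act over zero elapsed time.
* Empty windows yield an `inestimable` flag, never an exception; rank
  deficiency, perfect separation and non-convergence in any GLM are hard
  errors.

## The synthetic-data generator

`simulate_cohort()` builds the canonical two-visit (extensible to `K + 1`
visit) confounding structure: `L_0 ~ N(0, 1)`;
`L_k = rho * L_{k-1} + gamma * A_{k-1} + noise`; a logistic (or
linear-Gaussian) exposure model in the current confounder and previous
exposure; and a piecewise-constant additive hazard
`h0 + beta_L * L_current + exposure terms`, inverted at a single uniform
draw per subject. The same uniform and the same confounder innovations are
reused with all exposures forced to zero, giving a *coupled* counterfactual
time `T(0)` per subject that serves as ground truth for the survival
estimator at a fraction of the Monte-Carlo variance.

**Structural parameterization.** The configuration's `psi` matrix holds the
*structural* blips — the quantities g-estimation targets. For a delayed
effect these are not the raw hazard coefficients: because `A_k` shifts
`L_l` by `gamma * rho^(l-k-1)` exactly (linear dynamics, shared
innovations), the controlled direct effect of `A_k` on the window-`l`
hazard is the direct coefficient *plus* `beta_L * gamma * rho^(l-k-1)`.
The generator therefore uses hazard coefficients
`psi_k(l) - beta_L * gamma * rho^(l-k-1)` for `l > k`, so that the blip
equations above hold exactly by construction. Two useful identities follow:
with all structural blips zero the factual and counterfactual hazards
cancel algebraically and the coupled times coincide (to floating-point
association order), and the survival-ratio identity holds conditionally on
the measured history without any approximation. Additive hazards can go
negative; the generator floors them at zero and warns when the floor is hit
on more than 1% of subject-window evaluations — default settings keep
hazards positive essentially everywhere.

Default study conditions (used throughout the validation suite): two
visits at times 0 and 1, administrative end 2 (3 for the survival-curve
experiments, so curves can be read at `t = 1, 2, 3`), `n = 2000` per
replicate, exposure model `logit^{-1}(-1 + 0.8 L + 1.5 A_prev)` — giving
treatment prevalence and persistence in the range typical of registry
treatment data — `rho = 0.8`, `gamma = 0.5`, innovation SD 0.5, `h0 = 0.4`,
`beta_L = 0.1`, structural blips `(psi_0(0), psi_1(1), psi_0(1)) =
(0.10, 0.15, 0.05)`. `h0 = 0.4` is far above a realistic chronic-disease
death rate; it is chosen so that two time units of follow-up carry enough
events for a `n = 2000` replicate to be informative, which is what a
validation rig needs. The optional dropout process uses a log-linear
hazard `exp(-2.2 + 0.5 L + 0.3 A)` (roughly one in five subjects dropping
out over three time units).

What the generator does *not* emulate: unmeasured confounding (a violation
flag can be added by construction but is off by default — the identifying
assumption holds exactly), measurement error, informative visit schedules,
competing risks, and exposure misclassification. Passing validation on
these cohorts shows the estimator solves the right equations under its own
assumptions; it says nothing about robustness to their failure on real
data.

## Validation experiments

The test suite (`tests/testthat/test-acceptance.R`) and
`scripts/acceptance.R` recompute, from scratch, at these problem sizes:

* crude treated/untreated death rates and the one-period survival ratio
  from published count inputs;
* the worked expansion examples (8 copies for a failure at 3.7 under
  `C = 10, delta = 0.5`; 21 copies for a full survivor);
* score-solver agreement with a bisection oracle (20 rows) and gamma IRLS
  (60 rows, positive outcomes);
* blip recovery over 50 replicates of `n = 2000` (30 in the script),
  compared at three Monte-Carlo standard errors, with the naive
  covariate-adjusted per-window regression as the biased contrast for the
  delayed effect;
* null preservation at `n = 5000` with randomized exposure and a 60-draw
  bootstrap;
* grid-refinement stability (`delta` vs `delta/2`) over 50 replicates of
  `n = 1000`;
* counterfactual survival against the coupled oracle at `t = 1, 2, 3`,
  `n = 5000`, with and without covariate-dependent dropout;
* bit-identity of the pipeline with the censoring module on and off when
  censoring is purely administrative.

Replicate counts are scaled to keep each experiment in the tens of seconds
while leaving the Monte-Carlo yardsticks (3 MC SEs, 0.25 simulation SDs)
meaningfully tight.

## A worked fit

```{r, eval = FALSE}
cfg <- sim_config(n = 2000)
sim <- simulate_cohort(cfg, seed = 1)
fit <- fit_sncstm(sim$cohort, blip_spec(K = 1), sncstm_control())
fit <- bootstrap_sncstm(sim$cohort, fit, B = 200, seed = 2)
print(fit)
curve <- counterfactual_survival(sim$cohort, fit, times = seq(0, 2, 0.25))
```

Effect modification is requested through the specification, e.g.
`blip_spec(K = 1, modifiers = "L")` adds an `A * L` blip term per window and
the corresponding `L * (Q - s_k)` propensity covariate; an analysis that
constrains the effect profile to depend only on the time since exposure
uses `blip_spec(K, sharing = "by_lag")`, which stacks the per-window
expanded datasets and solves one score equation per lag.

## Known limitations

* The multiplicative survival model does not bound fitted survival
  probabilities by one; `counterfactual_survival()` warns and does not
  clip.
* The normalization of the weighted counterfactual average under dropout
  (sum of weights versus cohort size) is not pinned down by the estimand's
  description; the Hajek form is the default and both are available.
* Consistency of the propensity step relies on the linear-in-time intercept
  shift, which is exact in the Gaussian case and an approximation for the
  logit link at realistic effect sizes.
* Only equal-lag parameter sharing is supported, by design (see above).
* Categorical exposures with more than two levels, within-window
  time-varying effects, and nonlinear continuous-exposure effects are out
  of scope.
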