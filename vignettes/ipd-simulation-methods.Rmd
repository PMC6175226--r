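---
title: "Simulating and comparing one-stage and two-stage IPD meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and comparing one-stage and two-stage IPD meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Individual patient data (IPD) meta-analysis pools patient-level records
across studies instead of published summary estimates. Two analysis
traditions coexist. A *one-stage* analysis fits a single mixed-effects
regression over all patients, with study as the grouping level; a
*two-stage* analysis first fits an ordinary regression inside every study
and then pools the per-study coefficients with standard random-effects
meta-analysis weighting. The two traditions agree only under simplifying
assumptions, and their finite-sample performance — bias, error, coverage,
power, and how often the models converge at all — depends on the amount
and location of between-study heterogeneity, the number and size of
studies, and whether the estimand is a main effect or an interaction.

`ipdmetasim` provides the full machinery to study this by simulation: a
generative model for IPD with controllable heterogeneity, the one-stage
model family, the two-stage pipeline, performance metrics, and a
reproducible factorial harness.

## The generative model

Each dataset has `k` studies. Study `j` contributes `n_j` patients with

$$y_{ij} = (\gamma_0 + u_{0j}) + (\gamma_1 + u_{1j})\,g_{ij}
  + (\gamma_2 + u_{2j})\,x_{ij} + (\gamma_3 + u_{3j})\,g_{ij} x_{ij}
  + \varepsilon_{ij},$$

where `g` is a Bernoulli(0.5) exposure indicator, `x` a covariate
(standard normal, or Bernoulli for binary-by-binary interactions),
$\varepsilon_{ij} \sim N(0, \sigma_j^2)$, and the $u$'s are centred
between-study random effects, independent across components. Each
component's variance is set from a target I² through
$\tau^2 = I^2\sigma^2/(1 - I^2)$, so heterogeneity is always stated on
the familiar I² scale relative to the residual variance
(`sigma_mean = 1` in most settings). Study sizes are i.i.d. uniform
integers on `[0.5, 1.5]` times the stated mean — the generator we emulate
documents only "drawn from a uniform distribution" around a mean, and a
symmetric multiplicative band is the reading that preserves the mean; the
band is configurable.

Eight named settings (`setting_preset()`) vary one ingredient at a time:
the base case with coefficients `(1, 0.5, 0.3, 0)`; a small-study
selection filter; study-varying residual SD (normal, mean 1, SD 0.5,
truncated below at 0.05 to guarantee positivity); skew-normal random
effects; and four interaction-focused settings with coefficients
`(1, 1, 0.5, 0.4)` — continuous covariate, binary covariate, binary
covariate with per-study prevalence uniform on `[0, 1]`, and
heterogeneity on all four components (covariate and interaction I² fixed
at 50%).

### Design choices in the generator

* **Skew-normal random effects.** The skewness/kurtosis targets
  (skew 1, kurtosis 4) are met with a Fleishman cubic
  polynomial-of-normal transform, solved by damped Newton iteration on
  the moment equations and rescaled to the target variance. "Kurtosis 4"
  is read as *total* kurtosis (normal = 3, so excess 1): total kurtosis
  is the convention in the simulation software being emulated, and
  (skew 1, excess 1) sits inside the Fleishman-feasible region; a
  `kurtosis_convention` switch selects the excess reading instead.
* **Independent random effects in generation.** The one-stage analysis
  models may estimate a correlation between intercept and exposure
  random effects, but no generating correlation is stated anywhere, so
  the generator draws components independently (ρ = 0). This is the only
  reproducible default; model `c` still estimates an unstructured 2×2
  covariance, so the estimation machinery is exercised either way.
* **Degenerate studies are the fitters' problem.** Under varying
  covariate prevalence some studies are generated with a constant
  covariate. The generator emits them as-is; the fitters flag the
  affected study-specific terms as inestimable. This mirrors how such
  data arise in practice (single-sex trials) and is exactly what drives
  the convergence drop that setting exists to study.
* **Seeding.** A `scenario_spec` carries one replication seed;
  the harness derives per-(cell, iteration) seeds from a master seed by a
  deterministic integer mix kept below 2³¹, so cells can be run in any
  order, or in parallel, without stream overlap.

## The one-stage model family

Six mixed-model specifications (`onestage_model_spec()`) vary how the
intercept and covariate enter — one common fixed coefficient, one fixed
coefficient per study (indicator coding, no global intercept), or a
study-level random effect — around a random exposure effect; the
interaction, when present, is a common fixed effect for models `a`–`c`
and a random effect for `e`–`g`. Models with both a random intercept and
a random exposure effect (`c`, `f`) use an unstructured 2×2 covariance;
model `g` uses independent components across its four random terms,
because a full unstructured covariance at that complexity rarely
converges and no analysis we emulate reports one.

Estimation is maximum likelihood (`lme4::lmer`, `REML = FALSE`) — plain
ML is what the reference analyses ran — with REML available as an
option. Inference on the target coefficient is the Wald 95% interval
`estimate ± 1.96·se`, matching the default behaviour of the mixed-model
software this family is patterned on; no small-sample df correction is
applied.

**Convergence.** A fit counts as converged when the optimizer reports
success, no convergence warning survives one automatic refit with a
different optimizer, and the target coefficient has a finite positive
standard error. A *boundary* ("singular") fit — a variance component
estimated at exactly zero — counts as converged: it is a valid ML
solution, it is what likelihood software in routine use reports as a
converged fit, and under zero-heterogeneity scenarios roughly half of
all fits land there, so treating the boundary as failure would empty the
metric denominators precisely where the models behave best. The one
exception is an *unstructured* random-effects covariance estimated with
non-degenerate variances but a correlation at the ±1 boundary: the
correlation parameter then diverges in the unconstrained (atanh-type)
parameterization that optimizers and Wald inference use, which is the
mechanical signature of non-convergence in such software — with two
studies and a random intercept-slope pair this is in fact the typical
outcome, which is exactly the cell where the fully specified model is
known to break down. Such fits are recorded as non-converged. Studies
whose study-specific covariate column is inestimable are handled by
dropping the rank-deficient columns with a recorded note rather than
failing the fit.

## The two-stage pipeline

Stage one fits, per study, ordinary least squares of the outcome on
intercept, exposure and covariate (plus the product term when the target
is the interaction — main effects are re-estimated per study alongside
it). Stage two pools the target coefficients under the standard
random-effects model. Two heterogeneity estimators are provided:
the closed-form DerSimonian–Laird moment estimator

$$\hat\tau^2_{DL} = \max\!\left(0,\;
  \frac{Q - (k-1)}{\sum \hat w_j - \sum \hat w_j^2 / \sum \hat w_j}\right),
  \qquad \hat w_j = 1/\hat\sigma_j^2,$$

with $Q$ the inverse-variance-weighted sum of squared deviations from
the fixed-effect mean, and a REML estimator that maximizes the
restricted log-likelihood over $\tau^2 \ge 0$ by bounded 1-D
optimization (tolerance 1e-10, explicit boundary check at zero, DL
fallback if the search fails). REML is the harness default — it is what
the two-stage analyses we emulate ran — and DL is always available
alongside. The pooled CI is normal Wald without a Knapp–Hartung
adjustment, since none is stated for the analyses being emulated.
First-stage sampling variances are floored at 1e-12 so that noise-free
degenerate inputs (used in tests) keep finite weights. Two-stage
"non-convergence" means fewer than two estimable studies; the pooling
itself cannot fail.

## Metrics and the harness

Over replications of one cell, converged fits are aggregated into mean
bias (truth − estimate, signed), mean error (absolute), coverage of the
95% CI (closed interval), and power of the two-sided Wald test against a
stated null — 0 for the main-effect settings, 0.2 for the interaction
settings, so power levels stay informative rather than saturating.
Non-converged iterations are excluded from all four metric denominators
(the only choice that keeps the metrics well-defined) and reported
separately as a convergence rate, plus the combined display metric
`(coverage + power)/2`. Every model in a cell is fitted on the *same*
generated datasets, so model comparisons are paired.

The default factorial grid crosses nine size rows (total patients /
studies: 5000/10, 2000/4, 1000/2, 5000/20, 2000/8, 1000/4, 5000/50,
2000/20, 1000/10) with six (intercept, exposure) I² pairs ((0,0),
(.5,0), (0,.5), (⅓,⅓), (.5,.5), (⅔,⅔)); the interaction settings reuse
the same pairs, keeping covariate/interaction I² at their preset values.
Models `e`–`g` are enabled by default only for setting 8. The reference
study ran 1000 iterations per cell; that is hours of computation at full
grid, so `n_iterations` is configurable and the package's own acceptance
checks run at 100–500 replications with Monte-Carlo-width tolerances.

## What a green test does and does not establish

The generator *is* the stated world of the simulation study: correctly
specified linear models, normal (or moment-matched skew-normal) random
effects, independent components, missing nothing. Green parameter
recovery and nominal-coverage tests therefore establish internal
consistency of the machinery — not that any model is robust to real-data
features the generator omits: non-normal outcomes, informative study
sizes, patient-level missingness, more than one covariate, study-level
covariates, or confounding between covariate prevalence and effect size.
The selection filter is a proxy for publication bias, not a model of it:
it deterministically removes the `floor(0.2k)` studies with the smallest
size-rank + true-effect-rank sum (a composite was chosen because an
intersection of the two bottom-20% sets need not remove 20%), ranking on
*true* study effects because the filter acts at generation time.

## Known limitations

* Continuous outcomes only; logistic/Poisson one-stage analogues are out
  of scope.
* Model `g` with a fully unstructured 4×4 random-effects covariance is
  not attempted (switchable structure covers the 2×2 case).
* The REML second stage assumes known first-stage variances, as standard
  aggregate-data meta-analysis does.
* At very small `k` (2–4 studies) the one-stage random-intercept models
  frequently fail to converge — that behaviour is part of what the
  simulation is designed to expose, not a defect of the wrapper.
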