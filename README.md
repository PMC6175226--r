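# ipdmetasim

Simulation framework for comparing **one-stage** and **two-stage**
individual patient data (IPD) meta-analysis of a continuous outcome.

## The problem

When patient-level data are available from several studies, the analyst
can either fit one hierarchical mixed-effects regression over all
patients (one-stage), or fit an ordinary regression inside each study
and pool the per-study coefficients with random-effects meta-analysis
weights (two-stage). The approaches agree only under simplifying
assumptions; how they actually compare — in bias, absolute error,
coverage, power, and how often they converge — depends on the number and
size of studies, where between-study heterogeneity sits (intercept,
exposure, covariate, interaction), and whether the estimand is a main
effect or an interaction. `ipdmetasim` provides the machinery to study
this by Monte-Carlo simulation, for biostatisticians evaluating IPD
analysis strategies.

## The model

Patient *i* in study *j* is generated from

    y_ij = (γ0 + u0j) + (γ1 + u1j)·group_ij + (γ2 + u2j)·x_ij
           + (γ3 + u3j)·group_ij·x_ij + ε_ij,     ε_ij ~ N(0, σ_j²)

with centred random effects `u` scaled so each component hits a target
I² = τ²/(τ² + σ²). Eight named settings vary the ingredients: a base
case, small-study selection (publication-bias proxy), study-varying σ,
skew-normal random effects (Fleishman transform, skew 1 / kurtosis 4),
and four interaction-focused settings (continuous or binary covariate,
varying covariate prevalence, heterogeneity on all four components).

Analysis models: one-stage mixed models `a`–`c` and `e`–`g` (common,
study-specific or random intercepts and covariate effects around a
random exposure effect; fitted by ML with lme4, Wald 95% CIs) and the
two-stage model `d` (per-study OLS, then random-effects pooling with
the DerSimonian–Laird moment estimator

    τ²_DL = max{0, (Q − (k−1)) / (Σw_j − Σw_j²/Σw_j)},  w_j = 1/σ̂_j²

or REML, the default). Performance per cell: mean bias, mean error,
coverage, power (null 0 for main effects, 0.2 for interactions) and
convergence rate, over replications where every model sees the same
datasets.

## Worked example

```r
library(ipdmetasim)

spec <- setting_preset(1, n_studies = 10, mean_study_size = 250,
                       i2_intercept = 0.5, i2_exposure = 0.5, seed = 2026)
ds <- generate_ipd(spec)
ds
#> IPD dataset: 2540 patients in 10 studies
#>   study sizes 162-349; true exposure effects in [-0.892, 1.966]

fit_onestage(ds, onestage_model_spec("c"))
#> model c [exposure]: estimate 0.6737 (se 0.2713), 95% CI [0.1419, 1.2055], converged
fit_twostage(ds, "exposure")
#> model d [exposure]: estimate 0.6735 (se 0.2857), 95% CI [0.1134, 1.2336], converged
pool_DL(first_stage(ds, "exposure"))
#> DL pooled estimate: 0.6735 (se 0.2839), 95% CI [0.1172, 1.2299]
#>   tau2 = 0.78858, Q = 442.2942, k = 10
```

Both routes estimate the mean exposure effect γ1 (truth 0.5 here; with
I² = 0.5 at both levels the true per-study effects range over ±1, so a
single realization lands well off the mean). `tau2` is the estimated
between-study variance of the exposure effect; Q is Cochran's
heterogeneity statistic.

A small Monte-Carlo cell (50 replications, 8 studies × mean 250,
intercept I² = 0.5):

```r
res <- run_cell(1, n_studies = 8, mean_size = 250, i2_intercept = 0.5,
                n_iterations = 50, master_seed = 2026)
res$summary[, c("model", "mean_bias", "mean_error", "coverage",
                "power", "convergence_rate")]
#>   model mean_bias mean_error coverage power convergence_rate
#> 1     a  -0.00543     0.0830     1.00  0.34             1.00
#> 2     b   0.00105     0.0401     0.96  1.00             1.00
#> 3     c   0.01206     0.0362     1.00  1.00             0.16
#> 4     d   0.00140     0.0410     0.98  1.00             1.00
```

The common-intercept model `a` pays for ignoring intercept
heterogeneity (double the mean error, degraded power); the fully
specified models `b`/`c` and the two-stage model `d` are nearly
interchangeable on this cell. Model `c`'s low convergence rate reflects
its unstructured intercept–exposure covariance degenerating (|ρ̂| = 1)
when the exposure-level variance is not supported by the data — see the
methods vignette (`vignettes/ipd-simulation-methods.Rmd`) for the
convergence criterion and all other design choices.

Full factorial runs: `run_grid(grid_spec(settings = 1, n_iterations = 1000, master_seed = 1), out_dir = "results")`,
or from the shell via `Rscript inst/cli/ipdmetasim.R run-grid --config inst/extdata/example-grid.json --out-dir results`.

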