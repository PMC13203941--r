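# grbtrends

Demographic constraints on global trends in gender role beliefs (GRB):
an R package for estimating how population-level support for gender
equality in the public sphere changes over time, and how differential
population growth and differential fertility shape that change.

## Who this is for

Social scientists and demographers working with sparse multi-country
survey series (a handful of survey waves per country at irregular years)
who need population-representative belief trends and their demographic
decomposition, plus a fully synthetic test bed with known ground truth for
validating every step.

## What it computes

**Composite score.** Three ordinal survey items on women's equal place in
work, education and politics are each rescaled to 0–100 and averaged;
higher = more egalitarian. Reliability via Cronbach's alpha; a median split
(ties to the less egalitarian group) defines the belief subgroups used by
the fertility models.

**Trend model (MRP).** A Gaussian hierarchical generalized additive model
estimates smooth time trends for every country and age-sex group at once:
per-zone cubic B-spline smooths, country deviation smooths sharing one
common wiggliness penalty (hierarchical factor-interaction splines), six
age-sex effects with random country deviations. Fitting is REML via
`mgcv`; uncertainty comes from draws of the multivariate normal
approximation of the joint posterior. Poststratification on external
country–year–age–sex population counts turns cell predictions into
national, zonal, development-class and global means — for the "average
country" (equal weights) and the "average citizen" (population weights).

**Composition analysis.** A counterfactual global series with national
population shares frozen in the anchor year isolates how differential
population growth constrains the global trend, summarized by the relative
trend excess `100·((cfΔ)/(obsΔ) − 1)` computed per posterior draw.
Spearman correlations between national population size and mean GRB, and a
Bayesian measurement-error regression of log population growth on national
GRB (JAGS), complete the picture.

**Fertility models.** A hybrid within-between linear mixed model relates
women's completed fertility (children reported at age 40–49) to their own
GRB and their country's mean GRB simultaneously (`lme4`, random country
intercepts and GRB slopes). A Bayesian hierarchical age-specific-fertility-
rate model — the four-parameter peak schedule
`f(a) = c·exp(−((a−μ)/s(a))²)` with `s(a)=s1` before and `s2` after the
peak, Poisson likelihood on cumulative fertility — contrasts the low- and
high-GRB subpopulations in every country, yielding total fertility rate and
fertility-timing gaps with full posterior uncertainty. Its posterior is
sampled by a purpose-built adaptive blocked Metropolis-within-Gibbs sampler
(see the methods vignette).

**Synthetic data.** `scenario_config()` / `simulate_scenario()` generate
survey microdata and population tables with the full generative structure —
zone-nested country trends, age-sex strata, ordinal item discretization,
GRB-dependent population growth and fertility — with all ground truth
recorded, so parameter recovery, interval calibration and null behavior are
tested end to end.

## Worked example

```r
library(grbtrends)

sim   <- simulate_scenario(scenario_config(seed = 42))
zones <- sim$truth$countries[, c("country", "zone", "hdi_class")]

fit   <- grb_trend(sim$survey, zones)
fit
#> Hierarchical GRB trend model
#>   countries: 20  zones: 3  age-sex groups: 6
#>   cells: 438  respondents: 36500  residual SD: 27.39

draws   <- draw_posterior(fit, n_draws = 1000, seed = 1)
country <- poststratify(draws, build_weights(sim$population, "country"))
cf      <- counterfactual_series(country, sim$population)
cf
#> Observed global mean 1995 -> 2022: 49.7 -> 56.4
#> Counterfactual (composition fixed at 1995): 58.3
#> Relative trend excess: 28% [22%, 38%] (posterior median, 90% ETI)

women <- subset(sim$survey, sex == "female" & age >= 18 & age <= 49)
asfr  <- fit_asfr(women, seed = 1)
derive_metrics(asfr)
#> Fertility metrics (posterior mean [90% ETI]):
#>   TFR difference (low - high)             0.175 [0.079, 0.270]
#>   Age-at-0.5 gap (high - low, years)      1.366 [0.948, 1.790]
#>   Prop. countries: low group higher TFR   0.968 [0.800, 1.000]
#>   Prop. countries: low group earlier      0.996 [0.950, 1.000]
```

Reading the output: in this synthetic world the global average citizen
became more egalitarian by 6.7 points, but had the national composition of
the world's adult population stayed at its 1995 shares the increase would
have been 28% larger (8.6 points) — differential population growth held
the global trend back. Women in the less egalitarian subgroup have 0.18
more children and reach half a child per woman 1.4 years earlier, and both
orderings hold in almost all countries — close to the generator's true
contrasts of 0.17 children and 1.52 years.

`run_pipeline(run_config(...))` chains all stages (simulate → score →
trends → poststrat → composition → lmm → asfr → report) with one master
seed, writing validated CSVs, a JSON manifest, and a plain-text report.

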