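---
title: "Models and methods behind grbtrends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grbtrends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`grbtrends` implements an analysis pipeline for population-level gender role
beliefs (GRB): how a 0--100 composite belief score has moved over time across
countries, how differential population growth reshapes the global average,
and how beliefs relate to women's fertility level and timing. This vignette
describes each model, its assumptions, the tunable parameters, the synthetic
data the package tests itself against, and the numerical choices a user
should know about.

## The composite GRB score

Respondents answer three ordinal items about women's equal place in work,
education and politics. Each item is rescaled linearly so that its scale
minimum maps to 0 and its maximum to 100; the composite is the arithmetic
mean of the rescaled items, with higher values indicating more egalitarian
beliefs. With fewer than two of three items answered the composite is
treated as missing (configurable via `min_items`; the appropriate rule is a
judgement call because partially answered batteries carry less information
but discarding them loses respondents). Reliability is summarized by
Cronbach's alpha on listwise-complete rows; note that raw alpha is invariant
to per-item shifts and to a common rescaling, but not to rescaling items
individually.

The subgroup split used by the fertility models assigns scores *equal to or
below* the split value to the "low" (less egalitarian) group; the default
split value is the realized sample median of the analysis sample, a property
of the data rather than a constant of the method.

## The hierarchical trend model

`grb_trend()` fits a Gaussian hierarchical generalized additive model to
respondent scores:

* a smooth calendar-year effect per cultural zone (cubic B-splines, basis
  dimension `k_zone`, default 8, second-order difference penalty);
* country-specific smooth deviations from the zone curve, modeled as
  factor-interaction smooths (`k_country`, default 5) that share **one
  common wiggliness penalty** across countries and include penalized country
  intercepts and linear deviations, so data-poor countries shrink toward
  their zone;
* fixed effects for the six age-sex groups ({18--34, 35--59, 60+} x
  {female, male}) and random country deviations from them.

Smoothing and variance parameters are selected by restricted marginal
likelihood (REML) in `mgcv`. Basis dimensions are package defaults, chosen
to allow one or two turning points over a 28-year window; they are declared
configuration, not a reconstruction of any particular study's choices.

Two implementation details matter. First, respondents are aggregated to
country-year-age-sex cell means with weights equal to cell sizes and the
residual variance fixed at the pooled within-cell estimate; this is
likelihood-equivalent to the respondent-level fit (same coefficients, same
REML criterion up to a constant, same coefficient covariance) and makes
repeated fitting cheap enough for simulation studies. Second, spline knots
are spaced evenly over the full observation window rather than at data
quantiles, so the basis is well defined for countries observed in few
years and predictions extend over the whole window.

Inclusion rule: countries enter with at least `min_waves = 2` distinct
survey years spanning at least `min_span_frac = 25%` of the window;
excluded countries are reported, not silently dropped.

Uncertainty comes from `draw_posterior()`: coefficient vectors are sampled
from the multivariate normal approximation of the joint posterior (mean =
penalized fit, covariance = Bayesian covariance conditional on the selected
smoothing parameters) and pushed through the design to every
country-year-cell. Conditioning on the smoothing parameters ignores their
own uncertainty; this empirical-Bayes approximation is the default, and the
simulation suite checks that 90% intervals still attain 85--95% coverage of
true cell means at the default study size. `draw_posterior(...,
unconditional = TRUE)` switches to the smoothing-parameter-uncertainty-
corrected covariance (available under the default optimizer), which widens
intervals slightly and is worth using for strongly nonlinear functionals of
the draws, such as rank correlations across countries.

## Poststratification and aggregation

Model cells are reweighted by external population counts:
within-country age-sex shares give national means; national adult population
shares aggregate countries into zones, development classes, or the world.
Weighting is applied independently to every posterior draw, so all derived
quantities (changes, counterfactuals, correlations) propagate the full
uncertainty. Equal-tailed 90% intervals use percentile type 7 (linear
interpolation between order statistics), making summaries bit-reproducible.
The "average country" series (countries weighted equally) and the "average
citizen" series (population-weighted) are both reported; their divergence is
the compositional signal.

## Compositional counterfactual and growth regression

The counterfactual global series recomputes the population-weighted average
per draw with national shares frozen at the anchor year (1995). National
composition means country shares only: within-country age-sex weights follow
the observed year, isolating between-country compositional change from
within-country population aging. The headline statistic is the relative
trend excess, `100 * ((cf_end - obs_start) / (obs_end - obs_start) - 1)`,
computed per draw and summarized by the posterior median — the ordering
matters because the excess is a nonlinear ratio.

The growth regression treats the log adult population at the window end as
the outcome with the log start population as offset, and the national mean
GRB as a predictor observed with known measurement SD (the posterior spread
of the poststratified national mean). It is fit with JAGS using
weakly informative zero-centered priors whose scales come from the response
range; the latent-predictor prior is N(0, 2^2) on the standardized scale.
Predictions transform back to population growth factors via
`exp(alpha + beta * grb)`.

Per-draw Spearman correlations between population size and national GRB use
the same draw index across countries, preserving cross-country posterior
correlation; ties get average ranks. These intervals are conditional on the
realized set of countries — they quantify estimation uncertainty in the
national means, not sampling of countries from a super-population.

## The fertility mixed model

Completed fertility is proxied by the number of children reported by women
aged 40--49, taken from each country's most recent survey no older than
2010. The mixed model splits every predictor into a between-country
component (the country mean) and a within-country component (the individual
deviation); both enter as fixed effects, with random country intercepts and
random country slopes on the within-GRB component. Continuous predictors
are standardized to respondent-level mean 0, SD 1 before centering, so
coefficients are per-SD. Age is a pooled effect because the sample is
restricted to one age band. Model 1 has GRB only; model 2 adds age,
education, income and town size; model 3 adds religiosity (the mean of four
rescaled religiosity items). Children counts are modeled as Gaussian here
deliberately — the count treatment lives in the ASFR model. Estimation is
REML via `lme4`; p-values use a normal approximation on t-ratios, and the
conditional R^2 uses the variance-partition formulation
`(var_fixed + var_random) / (var_fixed + var_random + var_residual)` with
the random-effect contribution averaged over the realized design. Singular
variance components are reported as boundary estimates, not errors.

## The hierarchical ASFR model

Each woman aged 18--49 contributes her age and reported children count. The
number of children is Poisson with mean equal to her subgroup's cumulative
age-specific fertility rate (ASFR) up to her age — the sum of the schedule
over integer ages from the support minimum. The schedule is the
four-parameter peak function

`f(a) = c * exp(-((a - mu) / s(a))^2)`, `s(a) = s1` below the peak and `s2`
at or above it,

with height `c` (births per woman-year), peak age `mu`, and pre/post-peak
steepness `s1`, `s2`. The support is fixed at integer ages 15--49 even
though only women 18+ are observed, because children reported at 18 reflect
earlier fertility; the support is configurable.

Both GRB subgroups in every country get their own four parameters (eight per
country), drawn hierarchically around global subgroup means with normal
population distributions on `log c`, `mu`, `log s1`, `log s2` and half-t(3)
priors on the hierarchy SDs. Priors are weakly informative around typical
human fertility schedules (peak near 28 +/- 5 years, `c` near 0.15, `s1`
near 5 and `s2` near 9 years).

The posterior is sampled by an adaptive blocked Metropolis-within-Gibbs
sampler written in the package. Three features were chosen after profiling
the posterior geometry of this model:

1. the four parameters of each country-subgroup are proposed **jointly**
   with a per-block covariance adapted during warmup, because `c` with `s2`
   and `mu` with `s1` are strongly correlated under cumulative-only data;
2. **group translation moves** shift a subgroup's hierarchical mean and all
   its country parameters together, letting the whole hierarchy slide along
   the likelihood ridge on which the peak age trades off against the
   post-peak width;
3. an **interweaved rescaling move** jointly scales each hierarchy SD and
   its country deviations, which prevents the SDs from sticking near zero
   (the usual centered-parameterization funnel) when countries are truly
   homogeneous.

Adaptation stops after warmup, so the recorded chains are valid MCMC. Split
R-hat and effective sizes are computed for every stored parameter; fits warn
above R-hat 1.1 and abort above a configurable hard threshold.

Derived metrics are computed per draw: the total fertility rate (area under
the schedule), the age at which cumulative fertility reaches 0.5 children
per woman (linear interpolation between integer ages; undefined — and
excluded with a count — if the schedule never reaches 0.5), the
average-country contrasts between subgroups, and the proportion of countries
in which the low-GRB subgroup has higher and earlier fertility.

## The synthetic world

The generator (`scenario_config()`, `simulate_scenario()`) produces the
structure the models assume, with every latent quantity recorded for
recovery testing:

* 20 countries in three cultural zones by default; each country's latent
  trend is a scaled logistic zone curve plus a country intercept
  (SD 4 points) and a two-term smooth deviation; six age-sex strata with
  fixed offsets and country-level deviations;
* three ordinal items (2, 3 and 4 response levels) generated by adding
  person noise (SD 16) and item noise (SD 20) to the latent score and
  discretizing at fixed equal-width thresholds — at these settings the
  composite's reliability is about 0.65, matching what such three-item
  batteries typically achieve;
* sparse survey waves: 2--5 per country at heterogeneous gaps, redrawn until
  the first-to-last span covers at least 30% of the window so that default
  scenarios satisfy the trend model's inclusion rule;
* adult populations with log-linear growth whose total log growth falls by
  0.01 per point of 1995 GRB (plus country noise), producing the
  differential-growth signal the composition module measures;
* fertility via the ASFR link: subgroup schedules calibrated once so the
  low-GRB group's total fertility is 0.17 children higher and its
  age-at-half-child 1.52 years earlier — the effect sizes the fertility
  models are asked to recover;
* a dedicated mixed-model sample generator whose Gaussian outcome encodes
  within/between GRB effects of -0.102 and -0.622 per SD, with random
  country intercepts (SD 0.574), random slopes (SD 0.05) and residual SD
  1.205.

Because ground truth is stored on the *composite* scale (the latent mean
pushed through discretization via `expected_composite()`), recovery tests
compare models against exactly the quantity they estimate.

What the generator does not emulate: real questionnaire wording or sampling
frames, survey design weights beyond age-sex composition, item missingness
patterns, migration and mortality, or period-cohort fertility distortions.
Passing tests therefore demonstrate that the estimators recover the
structure they model, not that the model is a complete account of real
survey data.

## Numerical choices and degenerate inputs

* Percentiles: type 7 everywhere, documented and tested against the
  interpolation formula.
* Master seed with deterministically derived per-stage child seeds; a rerun
  reproduces outputs bit-for-bit, a seed change perturbs all stochastic
  stages.
* Degenerate designs are handled explicitly: one zone drops the zone terms,
  one country drops the country smooths, one age-sex level drops the group
  effects; a survey with no within-cell replication falls back to REML scale
  estimation with a warning.
* Ties in the subgroup split go to "low"; undefined timing metrics are
  excluded with a reported count; near-zero observed global change makes
  the relative excess unstable and is flagged rather than returned
  silently.

## Problem sizes used by the validation suites

The package's simulation studies run at reduced but honest sizes chosen as
package defaults: trend-coverage over 200 replicates of the default
scenario (20 countries x 2--5 waves x 500 respondents, 300 posterior
draws); 100 replicates of the mixed-model recovery at 100 countries x 150
women; 50 scaled-down hierarchical ASFR replicates (6 countries, 250 women
per country-subgroup, short adaptive chains) plus replicate-averaged
single-country recovery at 5,000 women per subgroup; and 25--40 replicates
for each null-calibration study. The acceptance script runs the full
pipeline once at the default scenario with 1,000 posterior draws.

## Known limitations

* Smoothing-parameter uncertainty is ignored by the normal approximation;
  coverage is verified by simulation rather than guaranteed.
* The trend model's Gaussian homoscedastic likelihood treats the 0--100
  composite as continuous; cell means make this accurate except in tiny
  cells.
* Children-ever-born by age is a period proxy; no tempo adjustment is
  applied.
* The growth regression conditions on the realized countries; it does not
  model country selection.
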