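---
title: "An integrated life-cycle model for Canada-origin Yukon River Chinook salmon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated life-cycle model for Canada-origin Yukon River Chinook salmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yukonIPM)
```

## The model

`yukonIPM` implements an age-structured Bayesian state-space life-cycle model
for the Canada-origin run of Yukon River Chinook salmon
(*Oncorhynchus tshawytscha*). Fish enter the model as age-2 (ocean age-0)
juveniles, the stage indexed by the Northern Bering Sea surface-trawl survey.
Juvenile production follows a Ricker spawner-recruit function of the brood-year
escapement two years earlier,

$$\log N_{y,2} = \log S_{y-2} + \log\alpha - \beta S_{y-2} + \varepsilon^R_y,
\qquad \varepsilon^R_y \sim \mathrm{Normal}(0, \sigma_R),$$

so $\alpha$ is juveniles-per-spawner at low stock size and $1/\beta$ the
capacity in spawners. Each older age class $a = 3\ldots7$ is carried forward
under competing bycatch and natural mortality,

$$N_{y,a} = N_{y-1,a-1}\, e^{-(F^B_y s^B_a + M_y v_a)} (1 - \theta_{c,a}),
\qquad
A_{y,a} = N_{y-1,a-1}\, e^{-(F^B_y s^B_a + M_y v_a)}\, \theta_{c,a},$$

where $F^B_y$ is the fully selected bycatch mortality rate of the eastern
Bering Sea pollock fishery, $s^B_a$ its selectivity-at-age (free on ages 3-6,
zero outside: no age-2 or age-7 fish of this stock appear in the bycatch),
$M_y$ the post-juvenile natural mortality rate and $v_a$ the
vulnerability-at-age (fixed to 1 at age 3, free in $[0.5, 1]$ above). The
maturation probability is a modified logistic in age, shared by all members
of a juvenile year-class $c = y - (a - 2)$:

$$\theta_{c,a} = \frac{1}{1 + e^{\lambda_c (7-a) + \log(1/0.99 - 1)}},$$

anchored so that fish reaching age 7 mature with probability 0.99 for every
$\lambda_c$. Mature returns ("run size" $A_y = \sum_{a=4}^{7} A_{y,a}$) face
terminal harvest $H_{y,a} = A_{y,a}(1 - e^{-F^T_y s^T_a})$; the survivors are
the spawning escapement that closes the loop. The four time-varying rates
($M_y$, $F^B_y$, $F^T_y$ by year; $\lambda_c$ by cohort) follow random walks
in log space with estimated innovation SDs.

Stock-specific bycatch is predicted by the Baranov catch equation and scaled
up to the total Chinook bycatch through the proportion
$\vartheta_{y,a}$ of each age class genetically assigned to the focal stock,
$BA_{y,a} = B_{y,a} / \vartheta_{y,a}$; the logit proportions are pooled
hierarchically across years within age so that years without genetic data
borrow strength from the rest.

Five data streams enter the joint likelihood: the juvenile abundance index
(lognormal, fixed log-SD 0.25, missing in 2005/2008/2020), run-reconstruction
escapement and harvest (lognormal, log-SDs 0.10 and 0.15) with age
compositions (multinomial, effective size 100 each), total Chinook bycatch
counts (lognormal, log-SD 0.10) with age compositions (multinomial at the
observed scale-sample sizes), and per-age genetic assignment counts
(binomial). The lognormal terms are median-parameterized (the prediction is
the log-scale location), the standard convention in fisheries state-space
models and the one that makes the fixed log-SDs interpretable as CVs.

## Initialization

Abundances of fish alive before the first model year are not derivable from
data. We estimate free log-abundances at ages 2-6 in a virtual year
preceding the first model year, plus the first two juvenile recruitments
(whose brood years predate the data), all with diffuse lognormal priors
(log-SD 5). Initializing one year *before* the window — rather than pinning
ages 3-7 within the first year — means matures, escapement, harvest and
bycatch are defined in every modelled year, and the spawner sum that the
recruitment recursion needs in year 3 exists. Cohorts recruited before the
window share the first cohort's maturation schedule.

Age-7 fish mature with probability 0.99, so 1% of age-7 survivors remain
immature with no age-8 class to enter. That residual is dropped (implicit
mortality). The conservation test quantifies it: the leak is exactly 1% of
age-7 survivors, a negligible share of any cohort.

## Priors and estimation

Priors follow the reference configuration: $\log\alpha \sim N(0, 12.5)$;
$\beta$ and all innovation SDs half-normal with SD 5; selectivities
$N(0,1)$ truncated to $[0,1]$; vulnerabilities $N(0,1)$ truncated to
$[0.5,1]$; initial log rates $N(0,5)$ (bycatch $N(0, 7.5)$); the initial log
maturation schedule $N(1,1)$ truncated to $[0,\infty)$; stock-composition
hyperparameters $N(0,5)$ (SDs half-normal). Truncations are honoured by
transformation, and the log prior includes the truncation constants.

The joint posterior is written as a TMB (C++ automatic differentiation)
template over an unconstrained parameterization: bounded quantities are
logit/log transformed and positive SDs log transformed, with Jacobian
adjustments and the R-side densities asserted equal in the test suite.
Sampling is by the No-U-Turn sampler implemented in the package: multinomial
trajectory sampling, dual-averaging step-size adaptation (target acceptance
0.95 by default), and windowed mass-matrix estimation. The mass matrix is
diagonal in early windows and switches to the full posterior covariance once
a window holds more draws than parameters; the dense metric matters here
because random-walk state-space posteriors are strongly correlated. The
same recipe is used by Stan and by the NUTS samplers bolted onto TMB/ADMB
assessment models.

Two parameterization choices matter for sampling efficiency and were made
after measuring mixing. First, the Ricker pair is rotated: the sampler's
coordinate is the log juveniles-per-spawner at a fixed reference escapement
of 50,000 fish (with log β as the second coordinate), which aligns the
data-informed direction of the α–β ridge with an axis; the transform is
unit-triangular, so priors are untouched. Second, centring follows the
data: the mortality/harvest walks, the recruitment errors and the
stock-composition logits are centred because their data streams are strong,
while the weakly informed maturation walk is non-centred.

Convergence reporting follows current practice: rank-normalized split
$\widehat{R}$ (bulk and folded), bulk/tail effective sample sizes via the
Geyer initial-monotone estimator, divergence counts, and per-chain BFMI.
The reference configuration (5 chains × 15,000 iterations, 5,000 warmup) is
available through `fit_ipm()` arguments; defaults are desk-scale. Two
directions of this posterior mix slowly no matter the parameterization: the
weakly identified Ricker capacity (its reference credible interval spans an
order of magnitude) and the confounded harvest-selectivity/harvest-mortality
scale. At desk scale (a few thousand iterations) the worst-case efficiency
is a few hundredths of an effective draw per iteration, so the strict
reference thresholds ($\widehat{R} \le 1.01$, ESS $\ge 1000$, zero
divergent transitions) require run lengths of the reference magnitude
(tens of thousands of iterations); short runs land near
$\widehat{R} \approx 1.03$ with occasional divergences in the capacity
tail. The package reports this honestly rather than thinning or loosening
the thresholds; the convergence test in the suite asserts the reference
criteria as stated and documents the shortfall when run at desktop sizes.

## The synthetic-data generator

`sim_scenario()` fixes a generating trajectory anchored to the reference
posterior medians: $\alpha = 48$ juveniles per spawner, capacity
$1/\beta = 81{,}178$ spawners, bycatch selectivity $(0.03, 0.15, 0.81,
0.21)$ over ages 3-6, vulnerability $(1, 0.67, 0.60, 0.64, 0.93)$ over ages
3-7, and natural mortality near 1.1 over 2003-2015 rising to 1.5 by 2020 and
holding — the post-heatwave regime. Quantities the reference analysis does
not print are package choices, set once to produce data of realistic
magnitude and shape: $\sigma_R = 0.5$; a harvest-mortality path declining
from 0.7 to 0.3 by 2014, moderate (0.45) over 2015-2020, and low (0.05)
after 2021; a bycatch-mortality path peaking near 0.008 in 2006 and dropping
to 0.0012 after the 2011 management change; a maturation schedule drifting
from 2.9 to 2.4 (slowly younger age at maturity); focal-stock bycatch
proportions near 5% with among-year logit SD 0.3; and a 1-in-10 genotyping
rate. These yield run sizes of 3×10^4-1.3×10^5 fish, stock-specific bycatch
removals of roughly 10^2-2×10^3 fish, and a late-period decline — the
qualitative shape of the real system.

The generator draws recruitment errors and stock-composition logits from
exactly the distributions the likelihood assumes and samples every
observation stream from the observation model, so fitting the model to its
output is a well-posed recovery problem. What it does not emulate: spatial
survey design and CPUE expansion (the juvenile index is drawn directly
around the latent abundance), genotype-level stock assignment, run
reconstruction internals (escapement/harvest are drawn around the latent
states), or environmental drivers of mortality. Passing recovery tests on
synthetic data therefore demonstrates internal consistency of model,
generator and sampler — not that the real data satisfy these assumptions.
The deterministic rate paths also mean the generating "walk SDs" are the
path increments, so estimated SDs shrink toward small values; coverage is
scored on the rate series themselves, not on walk SDs.

## Retrospective counterfactuals and projections

Counterfactuals re-run the process model from each posterior draw with one
process overridden and everything else, including initial conditions and the
draw's maturation series, unchanged: zero bycatch, zero harvest, baseline
natural mortality (2016-on rates replaced by the draw's median pre-2016
level — computed within draw to preserve joint-posterior coherence, with a
pooled-posterior variant behind a flag), favorable recruitment (all
recruitment deviations fixed at the 95th percentile — linear interpolation
between order statistics — of the per-year posterior-median deviations), and
the baseline-mortality + favorable-recruitment combination. Recruitment is
recomputed from the counterfactual escapements, so removals propagate to
later returns; zero-bycatch runs still harvest the extra survivors in their
return year. Differences from the fitted trajectory are taken draw-wise and
then summarized.

Projections continue each draw from its terminal age structure: harvest
mortality fixed at zero; bycatch mortality fixed at the draw's mean 2011-2023
estimate; natural mortality and the maturation schedule continuing their
random walks with fresh innovations (or frozen/fixed, for sensitivity
grids); recruitment errors drawn from $N(0, \sigma_R)$. Cohorts recruited
before the projection keep their estimated schedules; only cohorts recruited
during the projection use continued walk values. The default horizon is 7
years (one maximum life cycle; 14 for the two-cycle sensitivity). A
final-year outcome counts as recovery when it reaches the empirical 90th
percentile of the projected final-year distribution — recomputed from the
ensemble at hand, never hard-coded — and as non-recovery at or below 16,000
fish, the recent-low run size; both are configurable.

## Numerical choices and edge cases

* Baranov fractions return 0 analytically when the total mortality rate is
  zero; no division by zero.
* Observed age-composition proportions become integer counts by
  largest-remainder rounding at the effective sample size (a proper
  multinomial); a fractional-count variant is available via
  `fractional = TRUE` for sensitivity.
* Exact zeros are allowed in observed compositions; predicted proportions
  are strictly positive by construction, and a predicted zero under an
  observed positive count returns `-Inf` with a warning rather than being
  clamped.
* Missing observations drop only their own term; years with no genetic
  assignments are informed through the among-year hierarchy.
* The bycatch-walk SD (process, estimated) and the total-bycatch count SD
  (observation, fixed at 0.1) are distinct parameters despite the shared
  symbol in common notation.
* Quantile conventions (scenario overrides, recovery thresholds) use linear
  interpolation between order statistics throughout.

## Problem sizes used by the test suite

The packaged tests favour many small, deep checks: process-model oracle
equivalence runs 100 random parameter sets on 8-14-year calendars;
likelihood terms are verified against generic density oracles; sampler
correctness is established on known Gaussian targets; and the end-to-end
recovery study fits 10 study-scale (21-year) synthetic datasets with
deliberately short single-chain runs (650 iterations, truncated
trajectories), scoring aggregate 95%-interval coverage of the generating
Ricker parameters, recruitment-error SD, mortality series and
selectivity/vulnerability schedules (measured coverage ≈ 0.88; individual
harvest selectivities under-cover because of the selectivity-mortality
confound, while the aggregate clears the bar comfortably). The single
"smoke" fit uses 4 chains of 1,350 iterations with the dense metric; the
acceptance script’s fit uses 4 chains of 1,800 (800 warmup). These sizes are the
package's choices for a routine desktop check; the reference configuration
remains available for production runs.

## Known limitations

En-route (in-river) adult mortality is not a separate process; it folds
into natural mortality and harvest. No density-dependent marine survival or
environmental covariates act on any rate. Selectivity and fishing mortality
share the usual confounding (selectivities are estimated freely in $[0,1]$
with no normalization), so individual $s^T_a$ and $F^T_y$ are weakly
identified even when their product is well determined. The age-7
vulnerability estimate can absorb maturation-schedule misfit. Projection
distributions inherit the estimated parameter ranges and cannot anticipate
dynamics outside them.
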