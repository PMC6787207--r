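---
title: "Methods behind baitfate: models, generator design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind baitfate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitfate)
```

## The scientific problem

Colonially breeding wading birds (herons, egrets, ibises, storks) routinely
practice brood reduction: the smallest chicks are ejected or fall from the
nest when food cannot support the whole brood. At large colonies the fallen
nestlings form a dense, seasonally pulsed carrion resource. `baitfate`
packages an analysis pipeline for camera-monitored bait experiments that
quantify who consumes that resource — in the system this package models,
primarily Turkey Vultures and American Alligators on tree islands in a
subtropical wetland — and what the consumed energy is worth to the
scavenger populations.

The pipeline has five analysis stages, each exposed as ordinary functions
and orchestrated by `run_pipeline()`:

1. **Synthetic data generation** (`generate_sites()`,
   `generate_deployments()`, `simulate_fates()`): the original field data
   are not publicly archived, so a seeded generator reproduces the study's
   unit of observation — one record per deployed bait.
2. **Tabulation** (`consumer_crosstab()`, `size_class_crosstab()`,
   `stratum_proportion()`, `relative_risk()`, `latency_summary()`).
3. **Mixed-effects modelling** (`fit_binomial_glmm()`,
   `backward_stepwise()`, `predict_probability()`).
4. **Classical tests** (`pearson_chi_square()`, `anova_test()`,
   `spearman_rho()`).
5. **Energetics** (`energy_budget()`, `multi_year_summary()`,
   `percent_of_population()`).

## The consumption model

For a target scavenger (alligator or Turkey Vulture), each known-fate bait
$i$ contributes a Bernoulli outcome $y_i$ (consumed by the target or not),
modelled on the logit scale:

$$\operatorname{logit} P(y_i = 1) = \mathbf{x}_i^\top \beta
  + u_{w(i)} + v_{w(i), s(i)},
\qquad u_w \sim N(0, \sigma^2_w),\quad v_{ws} \sim N(0, \sigma^2_{s}),$$

with Gaussian random intercepts for week-of-season $w$ and for island $s$
within week — the "site nested in week" structure that absorbs
pseudo-temporal and pseudo-spatial correlation among baits deployed
together. All continuous covariates are z-scored (`scale_covariates()`);
colony type is coded *Ardea* = 0, *Egretta* = 1; understory complexity is
treatment-coded with `low` as reference. Two covariates of the same model
never enter with an absolute Spearman rank correlation above 0.5
(`collinearity_screen()`); when a pair exceeds the threshold the member
with the larger mean absolute rank correlation against the remaining
covariates is dropped, with ties resolved against the later covariate in
declared order — a deterministic rule where the field convention is silent.

### Estimation

The marginal likelihood integrates over the random intercepts; `baitfate`
maximises its **Laplace approximation**, implemented from scratch
(`glmm_laplace_fit()`):

* For candidate standard deviations $\theta = (\sigma_w, \sigma_s)$ a
  penalized iteratively reweighted least squares (PIRLS) finds the joint
  conditional mode of $(\beta, \mathbf{b})$, where $\mathbf{b}$ are
  spherical random effects ($\eta = X\beta + Z\Lambda(\theta)\mathbf{b}$,
  penalty $\|\mathbf{b}\|^2$). Each PIRLS step solves one penalized
  weighted least-squares system; the system is assembled dense for small
  problems and sparse (via the Matrix package) when the number of groups
  is large. Step-halving guards monotone descent, and the loop stops at a
  relative change in the penalized deviance below $10^{-10}$.
* The Laplace criterion is
  $-2\ell(\theta) = \text{dev} + \|\mathbf{b}\|^2 +
  \log\det(\Lambda^\top Z^\top W Z \Lambda + I)$.
  It is minimised over $\theta$ by a derivative-free Nelder–Mead search on
  $|\theta|$ — folding at zero makes a vanishing variance an interior
  point, so boundary fits ($\hat\sigma = 0$) are reachable and flagged.
  Because a Nelder–Mead simplex can collapse prematurely, the search is
  restarted from its own solution (up to twice) while a restart still
  improves the criterion; the relative convergence tolerance is
  $10^{-8}$. The linear algebra exploits the bordered structure of the
  penalized system: a sparse Cholesky factorisation of the
  random-effect block (which also yields the log-determinant) plus a
  dense Schur complement for the fixed effects.
* The joint-mode profile slightly attenuates $\beta$ relative to the exact
  Laplace optimum (it ignores the dependence of the log-determinant on
  $\beta$). A final **Newton polish** therefore refines $(\beta,
  \log\theta)$ against the criterion with only the random-effect mode
  profiled, using a finite-difference gradient and Hessian evaluated with
  every probe restarted from the central mode (warm-start hysteresis
  otherwise biases the differences). Against independent mixed-model
  implementations (lme4's `glmer` as a cross-check in the test suite;
  glmmTMB's exact-gradient Laplace during development) the polished
  estimates agree to about $10^{-3}$ on the logit scale and the
  criterion to about $10^{-2}$.
* **Wald standard errors** come from the observed information of the
  Laplace objective at the optimum. By default the information is taken
  jointly over $(\beta, \log\theta)$ (`se_method = "full"`), so the
  reported fixed-effect standard errors propagate variance-component
  uncertainty; `"conditional"` reproduces the cheaper conditional-on-
  $\theta$ errors. Variance components at the boundary are excluded from
  the differentiated parameters. $z = \beta/\mathrm{SE}$ and two-sided
  normal p-values mirror the conventional mixed-model output table.

With both variance components held at zero (`control =
list(theta_fixed = c(0, 0))`) the fitter reduces exactly to the package's
own plain logistic IRLS (`fit_logistic_glm()`), which is also kept as an
explicit, separately implemented oracle.

### The quadrature oracle

For single-level models the marginal likelihood is computable to machine
accuracy by **adaptive Gauss–Hermite quadrature** (`agq_loglik()`):
per-group one-dimensional Newton search for the integrand mode, curvature
rescaling, 50 Golub–Welsch nodes. It shares no code with the Laplace path
and anchors the oracle-equivalence tests. One practical subtlety governs
those tests: with Bernoulli clusters of about ten observations and
random-intercept sd near 0.5, the *approximation* gap between Laplace and
the exact likelihood is of order $10^{-2}$ — far larger than any sensible
implementation tolerance. The oracle-equivalence suite therefore draws
instances with information-rich binomial denominators (120–200) and sd at
most 0.2, where the measured approximation gap stays below $10^{-3}$, so
the comparison can detect implementation defects at that tolerance; a
looser sanity band is asserted for Bernoulli instances.

### Model selection

`backward_stepwise()` performs manual backward selection under AICc,

$$\mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1},$$

where $k$ counts fixed effects (intercept included) plus the two variance
components. At each step every single-covariate removal is refitted; the
removal that most reduces AICc is accepted, and selection stops when no
removal reduces AICc. The random structure is never a removal candidate.
Ties within $10^{-6}$ AICc are resolved by removing the covariate with the
larger Wald p-value; candidates that fail to converge are skipped and
logged in the selection trace. Note that a covariate can be retained while
marginally non-significant — selection is by information criterion, not
p-value, matching reported practice in this literature. Candidate fits
inside the stepwise loop use the fast path (no polish, conditional
standard errors): the selection decisions depend only on the criterion
values, which the polish does not alter materially.

## The synthetic-data generator

The generator emulates the study conditions, not any particular realised
dataset:

* **Design**: 26 active colonies (a 20/6 *Ardea*/*Egretta* split) and 6
  inactive islands; one to three visits per island at least two weeks
  apart; at most five baits per island-visit (per-visit counts are drawn
  with probability proportional to count, giving roughly 7.3 deployments
  per island, near the reported ~200 deployments for 32 islands); a
  ten-week season.
* **Covariates**: truncated normal draws using the published per-class
  mean, sd and range for distance to water, local nesting density (zero on
  inactive islands by definition), island area, colony size and stem
  density. Only mean ± sd and the observed range are printed for these
  fields, so a range-clipped normal is the assumed shape. Quantities with
  no printed summary use fixed, documented defaults: distance to canal
  (truncated normal, mean 500 m, range 0–2000 m), distance to the nearest
  alligator hole (mean 15 m, range 0–60 m), camera exposure time (mean
  7000 min, capped at the one-week camera window of 10,080 min), daily
  temperature as a seasonal linear trend (68 °F + 1.2 °F/week + N(0, 3)
  noise, in Fahrenheit to match the covariate's reported units), 27% of
  baits placed in water (54 of 200 deployed), and class-specific
  understory-complexity mixes.
* **Outcomes**: the two published binomial models cannot both act as
  conditional laws of a single exclusive outcome, so the generator uses a
  four-category logit over {not eaten, alligator, Turkey Vulture, pooled
  minor consumer}. The alligator and vulture channels reuse the published
  fixed-effect estimates verbatim plus their own week and island-in-week
  random intercepts; the not-eaten and minor-consumer baselines are
  calibration constants (−0.67 and −1.21) frozen once, by simulating the
  default design over a few dozen seeds, so that the marginal category
  frequencies match the observed consumer table (15% not eaten, 9.4%
  minor consumers; realised calibration: 14.6% and 9.0%, overall
  consumption 85.4%). The softmax competition slightly reallocates the
  alligator/vulture split relative to the two marginal binomials — that is
  the price of a well-defined exclusive outcome and is why coefficient-
  recovery validation uses `simulate_binomial_fates()`, which draws the
  target-vs-rest outcome from exactly the binomial mixed model being
  fitted.
* **Random-intercept sds** default to 0.5 on the logit scale at both
  levels. No group-level variance is reported for this system; 0.5 is a
  moderate, conventional choice (group odds ratios mostly within a factor
  of ~2.7) and is configurable.
* **Size classes**: conditional on an alligator consumer, the size class
  is drawn per island class from the jointly consistent subset of the
  printed size-class table (below).
* **Censoring**: each record's fate is unidentifiable with probability
  0.2, matching the reported 42 of 202 baits; censored records carry no
  consumer and are excluded from every analysis by
  `filter_known_fates()`.
* **Latency**: exponential with mean 48 h (the reported average latency of
  about two days) truncated at each bait's exposure window.

What the generator does **not** emulate: within-season nest phenology,
spatially explicit island maps, camera failure modes other than uniform
censoring, bait-to-bait interference, and any dependence of censoring on
covariates. Passing tests on synthetic data therefore demonstrate that the
machinery recovers known truth under the study's design — not that the
published field estimates are correct.

## The packaged fixtures

`consumer_table_fixture.csv` holds 202 deterministic records (160 known-fate, 42
censored) whose consumer tallies reproduce the published consumer table
exactly in every stratum. The printed alligator size-class table is
internally inconsistent with the consumer table — its active-island size
classes sum to 41 alligator-consumed baits against 43, and its *Ardea*
column sums to 139 baits against the 116 known-fate *Ardea* records — so
no record-level dataset can reproduce both tables fully. The fixture
reproduces the consumer table exactly plus the size-class cells that are
jointly consistent with it (28 large on active islands, 13 large and
61.90% on *Egretta* islands, the full inactive column), assigning the
remaining alligator records to the nearest consistent classes. The
verbatim printed size-class table ships separately
(`size_class_table_fixture.csv`, `size_class_table_printed()`), preserved as printed with no
reconciliation attempted. Consistency assertions in the test suite apply
to the consumer table only. One in-text percentage in the source results
("14% of all baits not consumed") contradicts the printed table's 24
unconsumed baits and is treated as a typographical error.

## Energetics

The budget converts annual nest starts into scavengers supported:

$$E_{\text{species,year}} = \text{nest starts} \times E_{\text{per nest}},
\qquad
N_{\text{supported}} = \frac{\sum_{\text{species}} E \times
r_{\text{scavenger, group}}}{\mathrm{DER} \times 60\ \text{days}}.$$

Per-nest energy (kJ) is the parameter unit because the upstream estimates
correct average nestling energy for observed chick mortality per nest.
Consumption rates $r$ default to the exact rational stratum proportions
from the consumer table (alligator: 26/116 for *Ardea*-like chicks, 17/21
for *Egretta*-like; vulture: 59/116 and 2/21), applying one rate per chick
group under the equal-rates assumption. Multi-year means average only the
years with nest-start estimates for every requested species; incomplete
years stay in the per-year table. All internal energy is in kJ; a GJ
aggregate is reported for cross-checking against the literature estimate
of roughly 17.4 GJ of fallen-nestling energy per season in this system.

The numeric parameter values shipped in
`energetics_params_synthetic.yaml` — per-nest energies (1200, 350, 1800
and 250 kJ for Great Egret, White Ibis, Wood Stork and the *Egretta*
group), daily energy requirements (300 kJ/day for an adult female
alligator, reflecting ectotherm maintenance metabolism; 800 kJ/day for an
adult Turkey Vulture, a typical field metabolic rate for a ~2 kg soaring
bird), and the synthetic nest-start series — are **synthetic placeholder
calibrations**, chosen once on those ecological grounds so that seasonal
available energy lands in the literature's order of magnitude. They are
not transcriptions of the original supplementary parameter set, which is
not publicly archived; analyses of real systems must replace them. The one
exception is the reference population of 1,131 adult female alligators,
which is implied exactly by the published pair of results (181 individuals
= 16% of the population). Consequently the *absolute* supported-scavenger
numbers produced from the packaged parameters are illustrative; the
module's contract is exact linearity, additivity and unit bookkeeping,
which the test suite verifies independently of parameter values.

## Numerical choices and degenerate inputs

* PIRLS tolerance $10^{-10}$ (relative penalized deviance), at most 60
  iterations; working weights floored at $10^{-12}$.
* Outer Nelder–Mead relative tolerance $10^{-8}$ with restart-until-stable;
  finite-difference steps for the polish/observed-information stage:
  0.02 on $\beta$, 0.05 on $\log\theta$, inner tolerance tightened to
  $10^{-12}$.
* Variance estimates below $10^{-3}$ sd are reported as boundary fits.
* Zero-variance covariates abort scaling with the offending name; rank
  collinearity ties break against declared order; stepwise AICc ties break
  toward the larger Wald p-value.
* Logistic IRLS declares (quasi-)separation when any coefficient passes 30
  on the logit scale and flags the fit as non-converged.
* The latency ANOVA helper supports one or two factors; with a single
  two-level factor it reproduces the F(1, n−2) layout used for the
  active-vs-inactive latency comparison.

## Validation scales

The test suite validates at the following problem sizes, chosen to give
each check real statistical power while keeping a full run on one CPU in
the tens of minutes: oracle equivalence on 100 random single-level
instances (≤ 60 observations each); coefficient recovery at the published
effect sizes on ~5,000-bait designs, 50 seeded replicates split across the
alligator and vulture models, requiring each coefficient within 2 SE of
truth in at least 90% of replicates; stepwise behaviour on ~2,000-bait
designs, 50 replicates, requiring null-covariate removal and
strong-covariate retention in at least 80%. The standalone
`scripts/acceptance.R` recomputes the same families of quantities at
reduced replicate counts (12 recovery replicates at ~2,000 baits, 15
stepwise replicates at ~1,000) so a full reproduction run stays within a
few minutes.

## Known limitations

* Laplace, not quadrature, is the production approximation (two nesting
  levels preclude simple quadrature); with Bernoulli clusters of ≤ 5
  baits its likelihood is a few hundredths off exact, and variance
  components are mildly attenuated — the recovery tests quantify the
  practical effect.
* Week-level inference rests on ~10 week groups; normal-theory intervals
  for the intercept and colony contrast are slightly anticonservative at
  that group count even with full-information standard errors. Two-SE
  coverage of a few terms in the recovery studies sits in the high 80s
  rather than at the nominal ~95% for the same reason; cross-checks
  against exact-gradient Laplace implementations show the reference
  tools behave identically under these conditions.
* Temperature is seasonally trending by construction (a linear function
  of week plus noise), so with week-level random intercepts its
  coefficient absorbs part of the realised week effects: its estimate
  carries extra variance in recovery studies, and it is unsuitable as an
  exchangeable "null" covariate in selection simulations — the distance
  covariates play that role instead.
* The generator's categorical outcome preserves the published covariate
  *effects* but not the exact marginal alligator/vulture split (see
  above).
* No random slopes, crossed random effects, Bayesian estimation or
  bootstrap inference; no spatial covariance beyond the nested intercepts.
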