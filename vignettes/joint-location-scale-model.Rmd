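---
title: "Joint mixed-effects location-scale models for repeated exposures and a distal outcome"
author: "jmels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint mixed-effects location-scale models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jmels)
```

## The scientific problem

When an exposure such as systolic blood pressure (SBP) is measured repeatedly
through childhood, three features of the individual's history might predict a
later outcome such as left ventricular mass (indexed to height, LVMI): the
individual's *mean level*, the *slope* of their trajectory, and their
*within-individual variability* — how much their measurements fluctuate
around their own trend from clinic visit to clinic visit. The common practice
of estimating per-person summaries first and regressing the outcome on them
(a two-stage analysis) is biased, because stage-one summaries carry sampling
error that stage two ignores; the variability summary is hit hardest, since a
log sample variance computed from a handful of visits is an extremely noisy
estimate of the person's true variability.

`jmels` implements the one-stage alternative: a joint mixed-effects
location-scale model in which the longitudinal and outcome submodels are
estimated simultaneously and share the individual-level random effects.

## The model

For individual $j$, clinic visit $i$ (at age $t_{ij}$) and within-clinic
occasion $h$:

$$
\begin{aligned}
y_{1hij} &= \mathbf{x}^{m\prime}_{ij}\beta + u_{0j} + u_{1j}\, z_{ij} + e_{ij} + \varepsilon_{hij},\\
e_{ij} &\sim N(0, \sigma^2_{e_{ij}}), \qquad
\log(\sigma^2_{e_{ij}}) = \mathbf{x}^{s\prime}_{ij}\alpha + u_{2j},\\
\varepsilon_{hij} &\sim N(0, \sigma^2_\varepsilon / n_{hij}),\\
y_{2j} &= \mathbf{x}^{o\prime}_{j}\gamma + \gamma_1 u_{0j} + \gamma_2 u_{1j} + \gamma_3 u_{2j} + u_{3j},
\qquad u_{3j} \sim N(0, \sigma^2_{u3}),
\end{aligned}
$$

with $(u_{0j}, u_{1j}, u_{2j}) \sim N(0, \Sigma_u)$ and $u_{3j}$ independent
of them by construction ($u_3$ never enters $\Sigma_u$; the corresponding
covariances are structural zeros). Here $z_{ij}$ is age centered at its grand
mean, $e_{ij}$ is the visit-to-visit fluctuation whose variance is modeled on
the log scale (the log link keeps it positive), and $\varepsilon_{hij}$ is
within-clinic measurement error; a stored value that is the mean of $k$ raw
readings carries $n_{hij} = k$ and error variance $\sigma^2_\varepsilon / k$.
A two-level variant (`levels = 2`) drops the $\varepsilon$ layer for designs
with one measurement per visit. The mean function uses a linear spline in age
with a knot at 12 years (`s1 = min(age, knot)`, `s2 = max(age - knot, 0)`, so
`s1 + s2 = age`), sex, sex-by-spline interactions, log body weight, height
and maternal covariates; the variance function uses age, sex, log weight and
height; the outcome function uses age and weight at the outcome visit and
sex. The exposure is in mm Hg; the outcome is modeled on the log scale, so
outcome-model coefficients are reported as percentage changes.

### Variable coding

All continuous covariates are grand-mean centered on the analysis sample;
the spline basis is computed on raw age and each basis column is then
centered, so the intercept is the mean exposure at the mean age. Weights are
log-transformed before centering. Sex is coded female = 1, male = 0.
Interaction columns are products of the centered components. Individuals
missing any covariate used by the active specification (or the outcome) are
dropped (complete case) with a logged count.

### Identification and the clinic-error layer

The clinic-level error $e_{ij}$ is never sampled: each visit's measurement
vector is marginally multivariate normal with a compound-symmetry covariance
$\sigma^2_{e_{ij}} J + \mathrm{diag}(\sigma^2_\varepsilon / n)$, which the
density code evaluates by a rank-one update, and which the sampler reduces
further to exact sufficient statistics (the pooled within-visit mean, and the
pooled within-visit sum of squares whose distribution is
$\sigma^2_\varepsilon \chi^2$). Separating $\sigma^2_{e}$ from
$\sigma^2_\varepsilon$ requires at least two measurements at (some) visits;
the cohort design provides two readings at every clinic except one, which
contributes its mean.

## Priors

Fixed effects carry normal priors: zero-centered except the three
intercepts, which are centered at crude empirical locations (the sample mean
of the exposure, the log of half its variance, the sample mean of the log
outcome), with scales set from empirical SDs (10 response SDs per column SD;
the variance-function coefficients use scale 2 on the log-variance scale).
The shared-effect loadings have mean-zero normal priors scaled so that one SD
of a latent effect can move the outcome by about one outcome SD. This is
deliberately tighter than the other coefficient priors: the log-variability
effect is weakly identified with few visits per person, and a very diffuse
loading prior places real posterior mass on configurations in which a large
loading and a distorted latent scale jointly overfit the outcome.

`sigma_eps` and `sigma_u3` have half-normal priors (scale: two response
SDs). `Sigma_u` has an inverse-Wishart prior with `df = 4` (the smallest
proper choice) and scale matrix set so the prior mode equals moment
estimates from a crude two-stage pass, *after subtracting the estimation
noise* those moment estimates carry (OLS sampling variances for the
intercept and slope; `trigamma(df/2)`, the variance of the log of a
chi-square, for the log residual variance). The inverse-Wishart was chosen
over a separation strategy (half-normal SDs with a uniform correlation
matrix) for two reasons established during development: it admits an exact
conjugate block update, and its density vanishes at singular matrices, which
removes the degenerate zero-variance configurations that otherwise act as
quasi-absorbing basins for any incremental sampler in this weakly identified
model. Its cost is a heavy right tail: with very weak identification the
variance components are pulled upward, which is visible as mild
finite-sample bias at small samples (below). All prior settings are
overridable through `fit_config(prior_spec = ...)`.

## The sampler

Estimation is by a blocked Gibbs/adaptive-Metropolis sampler written for
exactly this model:

* $(u_{0j}, u_{1j})$, $\beta$, $(\gamma, \gamma_{1..3})$ and $\Sigma_u$ have
  exact conjugate block draws;
* $u_{2j}$ is updated by a vectorized random-walk Metropolis step (all
  individuals proposed at once, accepted elementwise — valid because the
  $u_j$ are conditionally independent), refreshed `u2_refresh` times per
  iteration;
* $\alpha$ uses an adaptive multivariate random-walk whose proposal starts
  at the Fisher information of a log-variance regression
  ($\tfrac12 X_s'X_s$) and is re-estimated from the warmup history;
* $\alpha$ also gets a *ridge move*: a joint proposal shifting $\alpha$ and
  compensating each $u_{2j}$ by the individual's mean shift, which moves
  along the near-flat direction between the variance-function coefficients
  and the log-scale random effects;
* $\sigma_\varepsilon$ and $\sigma_{u3}$ use adaptive scalar Metropolis
  steps on the log scale;
* translation moves shift (intercept, $-u_0$), (both spline slopes, $-u_1$)
  and (variance intercept, $-u_2$) jointly, with the outcome intercept
  compensated through the loadings — these decorrelate the fixed intercepts
  from the random-effect means under the centered parameterization.

Proposal scales adapt by Robbins-Monro recursion during warmup only and are
frozen afterwards, so retained draws come from a fixed, valid kernel. During
the first half of warmup the outcome likelihood enters the latent-effect and
loading conditionals with a weight rising smoothly from 0 to 1, so the
longitudinal submodel burns in before the outcome feedback opens; every
retained draw targets the exact posterior. One master seed drives
everything; per-chain seeds are derived deterministically, and identical
data, configuration and seed reproduce the draws exactly.

### Validation

The sampler was validated four ways, all reproducible from the test suite:

* the complete-data density agrees with an independently coded
  explicit-covariance density to 10 decimal places, and the Gauss-Hermite
  marginal-likelihood oracle agrees with independent quadrature and with
  100,000-draw Monte-Carlo integration;
* strict simulation-based calibration: with generating parameters redrawn
  from the prior each replicate, the rank of every parameter's true value
  among its posterior draws is uniform (`calibration_study(truth_mode =
  "prior")`);
* fixed-truth calibration at the study design (20 replicates, J = 300):
  pooled 95% credible-interval coverage ≈ 92–93%;
* posterior means and SDs match an independent Gibbs implementation (JAGS,
  identical priors) to within a tenth of a posterior SD on every parameter
  on a shared test dataset — at roughly a third of the runtime.

### Convergence diagnostics and known mixing limits

`fit_mels` reports split-R-hat and effective sample size per parameter and
flags the fit when max R-hat exceeds 1.05. At the full cohort size
(J ≈ 2,000) the posterior is well behaved. At small J (a few hundred) with
all three effects shared, the log-variability block
(`sd(u2)`, its correlations, the `log_scale` loading, `sigma_u3`) mixes
slowly — the per-individual information about $u_{2j}$ from ~5 visits is
weak, so the likelihood is nearly flat along several ridges. Expect to need
a few thousand iterations per chain for R-hat ≤ 1.05 there; non-converged
fits complete but carry a warning and a failed flag in the convergence
report. This is a property of the model at that sample size, not of the
implementation (gradient-based samplers face the same geometry).

## The synthetic-data generator

`simulate_mels()` draws from exactly the model above, under a design that
emulates the motivating cohort: six clinics at mean ages 7.5, 9.5, 10.5,
11.5, 13 and 15.5 years (individual ages jittered with SD 0.25 y, a value
chosen as realistic since only the within-clinic age spread, not its
magnitude, is documented); two exposure readings per clinic except the
10.5-year clinic, which stores the mean of its two readings (recorded with
`n_pooled = 2`); independent per-clinic attendance with probabilities
matched to the cohort's per-clinic sample sizes (≈ 0.85–0.91, giving ~5.3
attended clinics per person and reproducing the ~10,556 visits / ~19,360
measurements scale at J = 2,000); and an outcome at age ≈ 17.7 y. The
default generating parameters are the fitted values reported for the
motivating cohort analysis: back-transformed from their percentage-change
scale where necessary, e.g. a log-variance age coefficient of
`log(1.1080)`, location/slope/log-variability SDs of 5.39 / 0.65 / 0.42,
correlations (−0.09, 0.50, −0.05), within-clinic SD 5.61, and outcome
loadings `log(1.0059)`, `log(1.0358)` and `log(0.9922)/log(1.10)`.

Covariates are synthetic stand-ins with realistic moments: sex ~
Bernoulli(0.549, female = 1); log weight and height grow linearly in age
with individual random intercepts; maternal age at delivery ~ N(29.5,
4.6²); parity ~ Poisson(0.7); maternal education sampled from the cohort
proportions. What the generator does *not* emulate: the real covariates'
joint dependence and their correlation with attendance, non-Gaussian
exposure tails, serially correlated within-individual errors, and
informative missingness. Passing tests therefore demonstrate correctness of
the machinery under the stated model, not robustness to those features of
real data.

The generator returns the latent truth (`u`, `e`, `sigma^2_e` per visit,
`u3`, `eps`) alongside the observable tables; the stored responses
reconstruct exactly from the truth plus the fixed parts, and
`moment_check()` compares the empirical exposure variance per clinic band
with the closed form
$\sigma^2_{u0} + z^2\sigma^2_{u1} + 2z\sigma_{u01} +
\exp(\mathbf{x}_s'\alpha + \sigma^2_{u2}/2) + \sigma^2_\varepsilon/n$
(the exponential term is the lognormal mean of the within-individual
variance).

## The two-stage comparator

`fit_two_stage()` implements the procedure the joint model replaces:
per-individual OLS of clinic-mean exposure on centered age (individuals with
fewer than 3 visits are flagged and excluded; exact-fit residual variances
are floored at 1e-8 before the log), then OLS of the log outcome on the
centered summaries plus the outcome covariates. `bias_experiment()` runs
replicated simulate-and-fit comparisons. With ~5 visits per person, the log
sample residual variance estimates the person's log variability with noise
variance ≈ trigamma(df/2) ≈ 0.8 — twice the signal variance (0.42² ≈ 0.18)
— so the two-stage log-variability coefficient is attenuated by roughly a
factor of five, while the joint estimator is approximately unbiased; in the
no-measurement-error, many-visit limit the two agree. Two-stage standard
errors also ignore the stage-one noise and understate the replicate-to-
replicate variability of the estimator.

## Numerical choices and degenerate inputs

* Log within-individual variances are clipped to ±30 inside density
  evaluations (with a warning) to prevent overflow during sampling.
* `Sigma_u` is accepted positive *semi*-definite by the constructor (the
  zero-variance limit is a valid generator setting); density evaluation
  requires strict definiteness and raises a definiteness error.
* `sigma_eps = 0` is accepted only with one measurement per visit.
* Ties at the spline knot: `s1 = min(age, knot)` puts `age = knot` in the
  lower piece; the two pieces always sum to age.
* The quadrature oracle costs `order^3` density evaluations per individual
  and warns below order 5; it is a testing device for ≤ ~10 individuals,
  never a production estimator.
* Outlier screening standardizes residuals from a fast homoskedastic
  three-level `lme4` fit at the measurement, clinic-visit and individual
  levels and removes records beyond a configurable threshold (default 4) —
  a reproducible proxy for visual quantile-quantile inspection.

## Problem sizes used by the checks

The replicated checks run at reduced scale, chosen as the smallest sizes at
which each property is informative: calibration uses 20 simulate-fit
replicates at J = 300 with 2 chains of 1,000 warmup + 1,500 sampling
iterations; strict SBC uses 20 replicates at J = 80 with a reduced
covariate set; the bias comparison uses 30 replicates at J = 250 with
single short chains (posterior means only); the moment check uses
J = 20,000; the likelihood oracles use 3 individuals. The full-cohort scale
(J = 2,000) is exercised once in the generator count checks.

## Known limitations

* Only Gaussian exposures and outcomes; no binary or time-to-event outcome
  submodels.
* No autocorrelated within-individual errors (relevant for intensive
  sampling designs).
* The variance function carries a random intercept only; random covariate
  coefficients inside the variance function are not supported.
* No imputation: complete-case analysis per the active specification.
* At small J the weakly identified variance-heterogeneity block mixes
  slowly and its posterior means show mild finite-sample bias (upward for
  `sd(u2)`, downward for `sigma_u3`) that vanishes as J grows; credible
  intervals remain approximately calibrated (pooled coverage ≈ 92–93% at
  J = 300).
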