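# jmels — joint mixed-effects location-scale models

`jmels` relates a repeatedly measured exposure to a later individual-level
outcome through a *joint mixed-effects location-scale model*: both the mean
trajectory of the exposure and the log of its within-individual
(visit-to-visit) variance carry fixed covariate effects and individual random
effects, and those random effects are shared as predictors of the distal
outcome. The motivating setting is childhood systolic blood pressure (SBP,
mm Hg), measured a couple of times per clinic visit at roughly six clinic
ages, and left ventricular mass indexed to height (LVMI, modeled on the log
scale) in early adulthood. The package is for biostatisticians and
epidemiologists who want to study within-individual variability as an
exposure in its own right without the bias of two-stage summaries.

## The model

For individual *j*, clinic visit *i* at age *t*, within-clinic occasion *h*:

    y1_hij = x_m' beta + u0_j + u1_j z_ij + e_ij + eps_hij
    e_ij   ~ N(0, s2_eij),   log(s2_eij) = x_s' alpha + u2_j
    eps_hij ~ N(0, sigma_eps^2)
    y2_j   = x_o' gamma + gamma1 u0_j + gamma2 u1_j + gamma3 u2_j + u3_j

with `(u0, u1, u2) ~ MVN(0, Sigma_u)` and the outcome residual `u3`
structurally independent of them. `z` is centered age; the mean function uses
a linear spline in age with a knot at 12 years; `e` is visit-to-visit
fluctuation whose variance is modeled on the log scale; `eps` is
within-clinic measurement error (a stored mean of *k* readings gets variance
`sigma_eps^2 / k`). Estimation is Bayesian, by a blocked Gibbs /
adaptive-Metropolis sampler written for this model (conjugate block draws for
the mean effects, location/slope effects, outcome effects and `Sigma_u`;
adaptive Metropolis for the variance-function block), with split-R-hat and
effective-sample-size diagnostics. A Gauss-Hermite quadrature oracle, a
synthetic-data generator that returns the latent truth, the two-stage
comparator, percentage-change reporting transforms and residual-based
outlier screening complete the toolkit. See the vignette
(`vignettes/joint-location-scale-model.Rmd`) for the statistical details.

## Worked example

Simulate a cohort-style dataset (300 individuals, six clinics between ages
7.5 and 15.5, two SBP readings per clinic with one clinic contributing only
its mean, log-LVMI outcome at ~17.7 years), fit the joint model, and print
the results table:

```r
library(jmels)

cfg <- mels_generator_config(n_individuals = 300, seed = 42)
sim <- simulate_mels(cfg)
sim
#> Synthetic joint-model dataset: 300 individuals, 1578 clinic visits, 2910 measurements (seed 42)

fit <- fit_mels(sim$data, cfg$spec,
                fit_config(chains = 2, warmup_draws = 1500, sampling_draws = 2500,
                           seed = 7, u2_refresh = 3),
                design = sim$design)
fit$convergence$max_rhat
#> 1.036

results_table(fit)[results_table(fit)$section != "mean function", ]
#>           section                 parameter             scale    mean    q2.5   q97.5
#>    random effects                    sd(u0)               raw  5.4458   4.907   6.042
#>    random effects                    sd(u1)               raw  0.5600   0.405   0.735
#>    random effects                    sd(u2)               raw  0.4504   0.319   0.626
#>    random effects                cor(u0,u1)               raw -0.1802  -0.443   0.100
#>    random effects                cor(u0,u2)               raw  0.1292  -0.185   0.436
#>    random effects                cor(u1,u2)               raw  0.0062  -0.401   0.448
#>    scale function               (Intercept)               raw  3.2350   2.999   3.464
#>    scale function                       age  percent_per_unit 15.5485   1.215  31.638
#>    scale function                    female  percent_per_unit  2.1740 -24.302  30.739
#>    scale function                log_weight percent_per_10pct  6.3540  -0.305  13.476
#>    scale function                    height  percent_per_unit -1.0262  -3.014   1.025
#>    scale function residual within-clinic SD               raw  5.7367   5.521   5.952
#>  outcome function               (Intercept)               raw  3.3152   3.281   3.350
#>  outcome function               age_outcome  percent_per_unit  1.3499  -5.693   8.696
#>  outcome function                    female  percent_per_unit -5.6344  -9.905  -1.198
#>  outcome function            weight_outcome  percent_per_unit  0.6858   0.517   0.850
#>  outcome function                  location  percent_per_unit  0.3047  -0.451   1.172
#>  outcome function                     slope  percent_per_unit -3.0312 -15.705  10.585
#>  outcome function                 log_scale percent_per_10pct -1.2545  -3.343   0.319
#>  outcome function               residual SD               raw  0.1899   0.154   0.214
```

Reading the table: individuals' SBP levels vary with SD ≈ 5.4 mm Hg
(generating value 5.39), their visit-to-visit variability is itself
heterogeneous (SD of the log variance ≈ 0.45 vs 0.42 generating), the
within-individual variance grows ≈ 15.5% per year of age (truth 10.8%) and
≈ 6.4% per 10% higher body weight (truth 5.24%), within-clinic measurement
error has SD ≈ 5.7 mm Hg (truth 5.61), and a 10% increase in
within-individual BP variance is associated with a −1.3% change in LVMI
(95% CrI −3.3% to +0.3%; generating value −0.78%). All generating values sit
inside their credible intervals here.

The same data analyzed with the biased two-stage shortcut attenuate the
variability-outcome coefficient by an order of magnitude:

```r
ts <- fit_two_stage(sim$data, cfg$spec)
unname(ts$loadings["log_scale"])
#> -0.0065      # generating coefficient: -0.0822
```

`bias_experiment()` repeats this comparison over replicated simulations;
`calibration_study()` runs replicated simulate-and-fit checks of interval
coverage; `screen_outliers()` removes residual outliers at the measurement,
clinic and individual levels before a final fit.

A thin command-line front end ships in `inst/cli/jmels`
(`simulate`, `fit`, `compare`, `report`).

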