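# Shared fixtures and independent oracles for the test suite. Heavy replicated
# studies (calibration, bias comparison) run once per session and are cached.

## ---- small hand-built dataset --------------------------------------------
tiny_tables <- function() {
  measurements <- data.frame(
    individual_id = rep(c("a", "b"), each = 4),
    clinic_id = rep(rep(1:2, each = 2), 2),
    occasion = rep(1:2, 4),
    value = c(100, 102, 110, 108, 95, 97, 99, 101))
  clinics <- data.frame(
    individual_id = rep(c("a", "b"), each = 2),
    clinic_id = rep(1:2, 2),
    age = c(10, 14, 10.5, 13.5),
    weight = c(30, 50, 32, 48),
    height = c(140, 160, 138, 158))
  individuals <- data.frame(
    individual_id = c("a", "b"),
    female = c(1, 0),
    age_outcome = c(17.5, 17.9),
    weight_outcome = c(60, 70),
    outcome = c(28, 31))
  list(measurements = measurements, clinics = clinics, individuals = individuals)
}

tiny_spec <- function(...) {
  mels_spec(mean_terms = c("s1", "s2", "female"),
            scale_terms = c("age", "female"),
            outcome_terms = "female", ...)
}

## The fixed small instance for the likelihood-oracle tests:
## 3 individuals, 2 clinics x 2 replicate readings each.
oracle_instance <- function(n = 3, seed = 101) {
  spec <- tiny_spec()
  cfg <- mels_generator_config(
    n_individuals = n, clinic_ages = c(10, 14), attendance = c(1, 1),
    reps_per_clinic = 2, pool_clinic = NA, spec = spec,
    true_params = default_true_params(spec), seed = seed)
  sim <- simulate_mels(cfg)
  list(sim = sim, design = sim$design, params = cfg$true_params, spec = spec)
}

## ---- independent density / integration oracles ---------------------------
## These build full covariance matrices explicitly and never reuse the
## package's density code path (which uses rank-one downdates and never forms
## a matrix).

dmvnorm_log_oracle <- function(y, mu, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

## Log density of one individual's measurements (+ outcome) at fixed u,
## built from an explicit block covariance: per clinic visit,
## s2e * J + diag(sigma_eps^2 / n_pooled).
oracle_individual_loglik <- function(design, params, j, u) {
  vis <- which(design$visit_individual == j)
  ll <- 0
  for (v in vis) {
    m <- which(design$meas_visit == v)
    s2e <- exp(sum(design$X_scale[v, ] * params$alpha) + u[3])
    mu <- sum(design$X_mean[v, ] * params$beta) + u[1] + u[2] * design$z_age[v]
    n <- length(m)
    Sig <- matrix(s2e, n, n)
    se2 <- if (is.na(params$sigma_eps)) 0 else params$sigma_eps^2
    diag(Sig) <- diag(Sig) + se2 / design$w_pooled[m]
    ll <- ll + dmvnorm_log_oracle(design$y1[m], rep(mu, n), Sig)
  }
  if (!is.na(design$y2[j])) {
    eta <- sum(design$X_outcome[j, ] * params$gamma)
    ucol <- c(location = 1, slope = 2, log_scale = 3)
    for (eff in design$spec$shared_effects)
      eta <- eta + params$loadings[[eff]] * u[ucol[[eff]]]
    ll <- ll + dnorm(design$y2[j], eta, params$sigma_u3, log = TRUE)
  }
  ll
}

## Independent 3-d Gauss-Hermite integration of the marginal likelihood.
oracle_marginal_gh <- function(design, params, order = 25) {
  gh <- pracma::gaussHermite(order)
  idx <- expand.grid(seq_len(order), seq_len(order), seq_len(order))
  x <- cbind(gh$x[idx[, 1]], gh$x[idx[, 2]], gh$x[idx[, 3]])
  logw <- log(gh$w[idx[, 1]]) + log(gh$w[idx[, 2]]) + log(gh$w[idx[, 3]])
  L <- t(chol(params$Sigma_u))
  total <- 0
  for (j in seq_len(nrow(design$X_outcome))) {
    ll <- vapply(seq_len(nrow(x)), function(k)
      oracle_individual_loglik(design, params, j, sqrt(2) * drop(L %*% x[k, ])),
      numeric(1))
    mx <- max(logw + ll)
    total <- total + mx + log(sum(exp(logw + ll - mx))) - 1.5 * log(pi)
  }
  total
}

## Monte-Carlo integration with standard error (per total log likelihood).
oracle_marginal_mc <- function(design, params, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  L <- t(chol(params$Sigma_u))
  total <- 0; var_log <- 0
  for (j in seq_len(nrow(design$X_outcome))) {
    u <- t(L %*% matrix(rnorm(3 * n_draws), 3))
    ll <- vapply(seq_len(n_draws), function(k)
      oracle_individual_loglik(design, params, j, u[k, ]), numeric(1))
    mx <- max(ll)
    w <- exp(ll - mx)
    est <- mean(w)
    total <- total + mx + log(est)
    ## delta method for the SE of log mean
    var_log <- var_log + stats::var(w) / (n_draws * est^2)
  }
  list(loglik = total, se = sqrt(var_log))
}

## ---- cached heavy studies -------------------------------------------------
.jmels_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .jmels_cache)) {
    assign(key, force(expr), envir = .jmels_cache)
  }
  get(key, envir = .jmels_cache)
}

## Criterion-level calibration study: 20 replicates at J = 300, study-design
## generator defaults, short chains.
get_calibration <- function() {
  cached("calibration", {
    cfg <- mels_generator_config(n_individuals = 300, seed = 1)
    calibration_study(cfg, n_replicates = 20, seed = 5,
                      joint_config = fit_config(chains = 2, warmup_draws = 1000,
                                                sampling_draws = 1500, seed = 1,
                                                u2_refresh = 3))
  })
}

## Two-stage vs joint bias comparison: 30 replicates of the cohort-like
## design (6 clinics, 2 readings) at J = 250.
get_bias_experiment <- function() {
  cached("bias", {
    cfg <- mels_generator_config(n_individuals = 250, seed = 1)
    bias_experiment(cfg, n_replicates = 30, seed = 11,
                    joint_config = suppressWarnings(
                      fit_config(chains = 1, warmup_draws = 350,
                                 sampling_draws = 350, seed = 1,
                                 u2_refresh = 3)))
  })
}

## A single well-mixed reference fit at the study scale.
get_reference_fit <- function() {
  cached("reference_fit", {
    cfg <- mels_generator_config(n_individuals = 300, seed = 42)
    sim <- simulate_mels(cfg)
    suppressWarnings(fit_mels(sim$data, cfg$spec,
                              fit_config(chains = 2, warmup_draws = 1500,
                                         sampling_draws = 2500, seed = 7,
                                         u2_refresh = 3),
                              design = sim$design))
  })
}
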