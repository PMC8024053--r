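# The exact probability model: predictors, log-variance function, complete-
# data density (clinic error marginalized), and the quadrature oracle, checked
# against independently coded full-covariance constructions.

manual_design <- function(ages = c(10, 13), y = c(0, 0)) {
  measurements <- data.frame(individual_id = "a", clinic_id = seq_along(ages),
                             occasion = 1, value = y)
  clinics <- data.frame(individual_id = "a", clinic_id = seq_along(ages), age = ages)
  individuals <- data.frame(individual_id = "a", outcome = NA_real_)
  d <- mels_data(measurements, clinics, individuals)
  spec <- mels_spec(mean_terms = "age", scale_terms = "age",
                    outcome_terms = character(0), shared_effects = character(0),
                    levels = 2)
  build_design(d, spec, require_outcome = FALSE)
}

test_that("mean predictor is the fixed part plus location and slope effects", {
  des <- manual_design(c(10, 13))  # centered ages -1.5, +1.5
  p <- mels_params(beta = c(100, 2), alpha = c(0, 0), gamma = 0,
                   Sigma_u = diag(3), sigma_u3 = 1)
  u0 <- mels_effects(matrix(0, 1, 3))
  expect_equal(mean_predictor(des, p, u0), c(100 - 3, 100 + 3))
  u <- mels_effects(matrix(c(3, -1, 0), 1))
  expect_equal(mean_predictor(des, p, u, visits = 2), 100 + 3 + 1.5 * (2 - 1))
  p_bad <- p; p_bad$beta <- c(100, 2, 1)
  expect_error(mean_predictor(des, p_bad, u), class = "jmels_contract_error")
})

test_that("log-variance function exponentiates the scale predictor", {
  des <- manual_design(c(10, 13))
  u0 <- mels_effects(matrix(0, 1, 3))
  p <- mels_params(beta = c(0, 0), alpha = c(0, 0), gamma = 0,
                   Sigma_u = diag(3), sigma_u3 = 1)
  expect_equal(log_within_variance(des, p, u0)$var, c(1, 1))
  p$alpha <- c(log(25), 0.1)
  sv <- log_within_variance(des, p, u0)
  expect_equal(sv$var, exp(log(25) + 0.1 * c(-1.5, 1.5)))
  ## positivity for arbitrary inputs (log link guarantee)
  set.seed(4)
  for (k in 1:20) {
    p$alpha <- rnorm(2, 0, 3)
    u <- mels_effects(matrix(rnorm(3), 1))
    expect_true(all(log_within_variance(des, p, u)$var > 0))
  }
})

test_that("outcome predictor adds only the shared-effect loadings", {
  tt <- tiny_tables()
  d <- mels_data(tt$measurements, tt$clinics, tt$individuals)
  spec <- mels_spec(mean_terms = "age", scale_terms = "age",
                    outcome_terms = "female", shared_effects = "log_scale")
  des <- build_design(d, spec)
  u <- mels_effects(rbind(c(0, 0, -2), c(0, 0, -2)))
  p <- mels_params(beta = c(0, 0), alpha = c(0, 0), gamma = c(3.3, 0),
                   loadings = c(log_scale = 0.5),
                   Sigma_u = diag(3), sigma_u3 = 1, sigma_eps = 1)
  expect_equal(outcome_predictor(des, p, u, spec), c(3.3 - 1, 3.3 - 1))

  p_bad <- p; p_bad$loadings <- c(log_scale = 0.5, location = 0.1)
  expect_error(outcome_predictor(des, p_bad, u, spec), class = "jmels_contract_error")

  spec0 <- spec; spec0$shared_effects <- character(0)
  p0 <- p; p0$loadings <- numeric(0)
  expect_equal(outcome_predictor(des, p0, u, spec0), c(3.3, 3.3))

  spec3 <- spec; spec3$shared_effects <- c("location", "slope", "log_scale")
  p3 <- p
  p3$loadings <- c(location = 0.1, slope = 0.2, log_scale = 0.3)
  p3$gamma <- c(0, 0)
  u1 <- mels_effects(rbind(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(outcome_predictor(des, p3, u1, spec3), c(0.6, 0.6))
})

test_that("single standard-normal measurement gives -log(2*pi)/2 plus prior", {
  des <- manual_design(ages = 10, y = 0)
  p <- mels_params(beta = c(0, 0), alpha = c(0, 0), gamma = 0,
                   Sigma_u = diag(3), sigma_u3 = 1)
  u <- mels_effects(matrix(0, 1, 3))
  ll <- complete_data_loglik(des, p, u)
  expect_equal(ll, -0.5 * log(2 * pi) + 3 * dnorm(0, log = TRUE))
})

test_that("complete-data density equals the explicit-covariance oracle", {
  oi <- oracle_instance()
  set.seed(8)
  u <- mels_effects(matrix(rnorm(9, 0, 0.5), 3))
  got <- complete_data_loglik(oi$design, oi$params, u)
  want <- sum(vapply(1:3, function(j)
    oracle_individual_loglik(oi$design, oi$params, j, u[j, ]), numeric(1))) +
    sum(vapply(1:3, function(j)
      dmvnorm_log_oracle(u[j, ], rep(0, 3), oi$params$Sigma_u), numeric(1)))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the density is unimodal in any single measurement coordinate", {
  oi <- oracle_instance()
  u <- mels_effects(matrix(0, 3, 3))
  des <- oi$design
  ll_at <- function(x) {
    des$y1[1] <- x
    complete_data_loglik(des, oi$params, u)
  }
  mode <- optimize(ll_at, interval = c(50, 170), maximum = TRUE)$maximum
  for (dir in c(-1, 1)) {
    prev <- ll_at(mode)
    for (shift in c(5, 15, 40)) {
      cur <- ll_at(mode + dir * shift)
      expect_lt(cur, prev)
      prev <- cur
    }
  }
})

test_that("invalid covariances are rejected", {
  expect_error(mels_params(beta = 0, alpha = 0, gamma = 0,
                           sd_u = c(1, 1, 1), cor_u = c(1.5, 0, 0),
                           sigma_u3 = 1),
               class = "jmels_definiteness_error")
  expect_error(implied_correlations(matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               class = "jmels_definiteness_error")
  expect_equal(unname(implied_correlations(diag(3))), c(0, 0, 0))
  S <- matrix(c(4, 2, 0, 2, 4, 0, 0, 0, 1), 3)
  expect_equal(unname(implied_correlations(S)), c(0.5, 0, 0))
})

test_that("quadrature oracle: self-consistency, MC agreement, permutation symmetry", {
  oi <- oracle_instance()
  gh15 <- marginal_loglik_gh(oi$design, oi$params, order = 15)
  gh25 <- marginal_loglik_gh(oi$design, oi$params, order = 25)
  expect_lt(abs(gh15 - gh25) / abs(gh25), 1e-6)

  mc <- oracle_marginal_mc(oi$design, oi$params, n_draws = 2e4, seed = 2)
  expect_lt(abs(gh25 - mc$loglik), 3 * mc$se)

  ## relabeling individuals leaves the likelihood unchanged
  d <- oi$sim$data
  relabel <- c(id00001 = "zz", id00002 = "aa", id00003 = "mm")
  m <- d$measurements; m$individual_id <- relabel[m$individual_id]
  cl <- d$clinics; cl$individual_id <- relabel[cl$individual_id]
  ind <- d$individuals; ind$individual_id <- relabel[ind$individual_id]
  des2 <- build_design(mels_data(m, cl, ind), oi$spec,
                       centers = oi$design$centers)
  expect_equal(marginal_loglik_gh(des2, oi$params, order = 15), gh15,
               tolerance = 1e-10)

  expect_warning(marginal_loglik_gh(oi$design, oi$params, order = 3),
                 "unreliable")
})

test_that("vanishing random effects reduce the marginal to the conditional at u = 0", {
  oi <- oracle_instance()
  p <- oi$params
  p$Sigma_u <- diag(1e-10, 3)
  u0 <- mels_effects(matrix(0, 3, 3))
  marg <- marginal_loglik_gh(oi$design, p, order = 15)
  cond <- complete_data_loglik(oi$design, p, u0) -
    sum(jmels:::dmvn_log(matrix(0, 3, 3), p$Sigma_u))
  expect_equal(marg, cond, tolerance = 1e-6)
})

test_that("zero scale covariates and zero u2 variance give the homoskedastic model", {
  ## With alpha = (a0, 0) and Var(u2) ~ 0 the exposure is a plain growth curve:
  ## y_j ~ MVN(X beta, Z Sigma01 Z' + (exp(a0) + sigma_eps^2) I) per individual
  ## (one measurement per visit here), checked against a direct MVN density.
  spec <- mels_spec(mean_terms = "age", scale_terms = "age",
                    outcome_terms = character(0), shared_effects = character(0))
  cfg <- mels_generator_config(
    n_individuals = 4, clinic_ages = c(8, 10, 12, 14, 16),
    attendance = rep(1, 5), reps_per_clinic = 1, pool_clinic = NA,
    outcome_missing_rate = 1, spec = spec,
    true_params = mels_params(
      beta = c(108, 1.5), alpha = c(2.5, 0), gamma = 3.3,
      sd_u = c(5, 0.6, 1e-6), cor_u = c(-0.1, 0, 0),
      sigma_u3 = 0.2, sigma_eps = 4),
    seed = 13)
  sim <- simulate_mels(cfg)
  des <- sim$design
  p <- cfg$true_params
  got <- marginal_loglik_gh(des, p, order = 25)
  want <- 0
  for (j in 1:4) {
    vis <- which(des$visit_individual == j)
    m <- which(des$meas_visit %in% vis)
    Z <- cbind(1, des$z_age[vis])
    Sig <- Z %*% p$Sigma_u[1:2, 1:2] %*% t(Z) +
      diag(exp(p$alpha[1]) + p$sigma_eps^2, length(vis))
    mu <- drop(des$X_mean[vis, ] %*% p$beta)
    want <- want + dmvnorm_log_oracle(des$y1[m], mu, Sig)
  }
  expect_equal(got, want, tolerance = 1e-5)
})
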