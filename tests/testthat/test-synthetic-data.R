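# The generator draws from the exact generative process; these tests pin the
# determinism contract, degenerate limits, design template counts, and the
# consistency between observable tables and the stored latent truth.

test_that("the generator is deterministic in its seed", {
  cfg <- mels_generator_config(n_individuals = 50, seed = 7)
  a <- simulate_mels(cfg)
  b <- simulate_mels(cfg)
  expect_identical(a$data$measurements, b$data$measurements)
  expect_identical(a$data$clinics, b$data$clinics)
  expect_identical(a$data$individuals, b$data$individuals)
  cfg2 <- cfg; cfg2$seed <- 8
  expect_false(identical(simulate_mels(cfg2)$data$measurements$value,
                         a$data$measurements$value))
})

test_that("zero variances collapse the data onto the fixed parts", {
  spec <- tiny_spec()
  ## "all variances zero": zero random-effect covariance, zero outcome and
  ## measurement SDs, and a log-variance intercept of -30 (variance ~ 1e-13,
  ## the smallest the clipped scale function represents)
  p <- mels_params(beta = c(108, -0.5, 3.8, -0.2), alpha = c(-30, 0, 0),
                   gamma = c(3.3, -0.05),
                   loadings = c(location = 0.006, slope = 0.03, log_scale = -0.08),
                   Sigma_u = matrix(0, 3, 3), sigma_u3 = 0, sigma_eps = 0)
  cfg <- mels_generator_config(n_individuals = 20, clinic_ages = c(10, 14),
                               attendance = c(1, 1), reps_per_clinic = 1,
                               pool_clinic = NA, spec = spec, true_params = p,
                               seed = 4)
  sim <- simulate_mels(cfg)
  zero_u <- mels_effects(matrix(0, nrow(sim$design$X_outcome), 3))
  fix <- mean_predictor(sim$design, p, zero_u)
  expect_equal(sim$design$y1, fix[sim$design$meas_visit], tolerance = 1e-5)
  eta <- outcome_predictor(sim$design, p, zero_u, spec)
  expect_equal(sim$design$y2, eta, tolerance = 1e-12)
})

test_that("a non-PSD true covariance is rejected before any draw", {
  expect_error(
    mels_generator_config(n_individuals = 5,
                          true_params = mels_params(
                            beta = 0, alpha = 0, gamma = 0,
                            sd_u = c(1, 1, 1), cor_u = c(1.5, 0, 0),
                            sigma_u3 = 1, sigma_eps = 1)),
    class = "jmels_definiteness_error")
})

test_that("the cohort design template produces the expected scale of counts", {
  sim <- simulate_mels(mels_generator_config(n_individuals = 2000, seed = 31))
  v <- sim$data$validation
  ## expected visits = 2000 * sum(attendance) = 10630; measurements =
  ## 2 * visits - visits at the pooled-mean clinic (~ 0.882 * 2000)
  expect_gt(v$n_clinic_visits, 10630 * 0.97)
  expect_lt(v$n_clinic_visits, 10630 * 1.03)
  exp_meas <- 2 * v$n_clinic_visits - sum(sim$data$clinics$clinic_id == 3)
  expect_equal(v$n_measurements, exp_meas)
  ## pooled clinic stores one row per visit with n_pooled = 2
  pooled <- sim$data$measurements$clinic_id == 3
  expect_true(all(sim$data$measurements$n_pooled[pooled] == 2))
  expect_true(all(sim$data$measurements$n_pooled[!pooled] == 1))
})

test_that("observable tables reconstruct exactly from the latent truth", {
  cfg <- mels_generator_config(n_individuals = 120, seed = 17)
  sim <- simulate_mels(cfg)
  p <- cfg$true_params
  des <- sim$design
  mu <- mean_predictor(des, p, sim$truth$u)
  y1_rebuilt <- mu[des$meas_visit] + sim$truth$e[des$meas_visit] + sim$truth$eps
  expect_equal(des$y1, y1_rebuilt, tolerance = 1e-12)
  eta <- outcome_predictor(des, p, sim$truth$u)
  expect_equal(des$y2, eta + sim$truth$u3, tolerance = 1e-12)
  ## stored within-individual variances match the scale function
  expect_equal(sim$truth$s2e,
               log_within_variance(des, p, sim$truth$u)$var, tolerance = 1e-12)
})

test_that("attendance thinning never removes the outcome row", {
  cfg <- mels_generator_config(n_individuals = 400, seed = 23,
                               attendance = rep(0.5, 6))
  sim <- simulate_mels(cfg)
  ## every individual with any clinic visit keeps an individual row + outcome
  expect_setequal(unique(sim$data$clinics$individual_id),
                  sim$data$individuals$individual_id)
  expect_true(all(!is.na(sim$data$individuals$outcome)))
  ## outcome missingness is a separate, configurable mechanism
  cfg2 <- mels_generator_config(n_individuals = 400, seed = 23,
                                outcome_missing_rate = 0.3)
  sim2 <- simulate_mels(cfg2)
  expect_gt(sum(is.na(sim2$data$individuals$outcome)), 0)
  expect_setequal(unique(sim2$data$clinics$individual_id),
                  sim2$data$individuals$individual_id)
})

test_that("per-individual mean and log-variance summaries correlate positively", {
  ## mirrors (qualitatively) the positive location/log-scale correlation:
  ## sigma_u02 > 0 in the generating covariance
  sim <- simulate_mels(mels_generator_config(n_individuals = 3000, seed = 29))
  s1 <- stage_one(sim$data)
  ok <- !s1$flagged
  expect_gt(cor(s1$intercept[ok], s1$log_resid_var[ok]), 0.1)
})

test_that("empirical moments match the closed-form marginal variance", {
  sim <- simulate_mels(mels_generator_config(n_individuals = 10000, seed = 37))
  mc <- moment_check(sim)
  expect_equal(nrow(mc), 6)
  expect_true(all(abs(mc$rel_error_var) < 0.05))
  expect_true(all(abs(mc$rel_error_mean) < 0.02))
})
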