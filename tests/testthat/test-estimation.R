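# MCMC estimation: determinism, diagnostics contracts, factorization when no
# random effects are shared, posterior contraction, strict simulation-based
# calibration with prior-drawn truths, and the shared-effect variant table.

quick_cfg <- function(J, seed = 1, ...) {
  spec <- tiny_spec()
  mels_generator_config(n_individuals = J, spec = spec,
                        true_params = default_true_params(spec), seed = seed, ...)
}

test_that("identical seed, config and data give identical draws", {
  sim <- simulate_mels(quick_cfg(40, seed = 2))
  fc <- fit_config(chains = 2, warmup_draws = 100, sampling_draws = 100, seed = 99)
  f1 <- suppressWarnings(fit_mels(sim$data, sim$config$spec, fc))
  f2 <- suppressWarnings(fit_mels(sim$data, sim$config$spec, fc))
  expect_identical(as.matrix(f1$draws), as.matrix(f2$draws))
  fc2 <- fc; fc2$seed <- 100
  f3 <- suppressWarnings(fit_mels(sim$data, sim$config$spec, fc2))
  expect_false(identical(as.matrix(f1$draws), as.matrix(f3$draws)))
})

test_that("configuration and input contracts are enforced", {
  expect_warning(fit_config(chains = 1), "single chain")
  expect_error(fit_config(chains = 2, warmup_draws = 0),
               class = "jmels_contract_error")
  empty <- mels_data(data.frame(individual_id = character(0),
                                clinic_id = character(0), occasion = integer(0),
                                value = numeric(0)),
                     data.frame(individual_id = character(0),
                                clinic_id = character(0), age = numeric(0)),
                     data.frame(individual_id = character(0)))
  expect_error(fit_mels(empty, tiny_spec()), class = "jmels_input_error")
})

test_that("convergence diagnostics reject single chains and flag degenerate ones", {
  sim <- simulate_mels(quick_cfg(40, seed = 2))
  fc <- suppressWarnings(fit_config(chains = 1, warmup_draws = 50, sampling_draws = 50, seed = 1))
  fit1 <- suppressWarnings(fit_mels(sim$data, sim$config$spec, fc))
  expect_error(convergence_report(fit1), class = "jmels_input_error")

  const <- coda::mcmc.list(coda::mcmc(matrix(1, 100, 2, dimnames = list(NULL, c("a", "b")))),
                           coda::mcmc(matrix(1, 100, 2, dimnames = list(NULL, c("a", "b")))))
  expect_warning(rep <- convergence_report(const), "degenerate")
  expect_true(all(!is.finite(rep$rhat)))

  fit2 <- get_reference_fit()
  rep2 <- convergence_report(fit2)
  expect_lte(attr(rep2, "max_rhat"), 1.05)
  expect_true(attr(rep2, "converged"))
})

test_that("with no shared effects the longitudinal posterior decouples from the outcome", {
  sim <- simulate_mels(quick_cfg(80, seed = 6))
  spec0 <- sim$config$spec
  spec0$shared_effects <- character(0)
  fc <- fit_config(chains = 2, warmup_draws = 400, sampling_draws = 400, seed = 3)
  f_joint <- suppressWarnings(fit_mels(sim$data, spec0, fc))

  ## same model with the outcome removed entirely
  ind <- sim$data$individuals
  ind$outcome <- NULL
  d0 <- mels_data(sim$data$measurements, sim$data$clinics, ind)
  f_long <- suppressWarnings(fit_mels(d0, spec0, fc))

  long_pars <- grep("^(beta|alpha|sd|cor)|sigma_eps", f_long$summary$parameter,
                    value = TRUE)
  a <- f_joint$summary[match(long_pars, f_joint$summary$parameter), ]
  b <- f_long$summary[match(long_pars, f_long$summary$parameter), ]
  mcse <- sqrt(a$sd^2 / pmax(a$ess, 4) + b$sd^2 / pmax(b$ess, 4))
  expect_true(all(abs(a$mean - b$mean) < 4 * mcse))
})

test_that("credible intervals contract as the sample size doubles", {
  fc <- fit_config(chains = 2, warmup_draws = 400, sampling_draws = 400, seed = 5,
                   u2_refresh = 3)
  widths <- function(J) {
    out <- NULL
    for (r in 1:6) {
      sim <- simulate_mels(quick_cfg(J, seed = 100 * J + r))
      fit <- suppressWarnings(fit_mels(sim$data, sim$config$spec, fc, design = sim$design))
      s <- fit$summary
      fixed <- grepl("^(beta|alpha|gamma)\\[", s$parameter)
      w <- s$q97.5[fixed] - s$q2.5[fixed]
      out <- rbind(out, setNames(w, s$parameter[fixed]))
    }
    colMeans(out)
  }
  w50 <- widths(50)
  w100 <- widths(100)
  expect_true(all(w100 < w50))
})

test_that("prior-drawn simulation-based calibration ranks are uniform per parameter", {
  spec <- tiny_spec()
  prior <- list(beta_mean = c(108, -0.5, 3.8, 0), beta_sd = c(3, 0.5, 0.5, 1),
                alpha_mean = c(3.1, 0.1, 0.2), alpha_sd = c(0.5, 0.1, 0.3),
                gamma_mean = c(3.3, -0.05), gamma_sd = c(0.3, 0.1),
                loading_sd = c(0.02, 0.1, 0.2),
                sigma_eps_scale = 6, sigma_u3_scale = 0.25,
                Sigma_df = 4, Sigma_scale = 8 * diag(c(25, 0.4, 0.2)))
  cfg <- mels_generator_config(n_individuals = 80, spec = spec,
                               true_params = default_true_params(spec), seed = 1)
  jc <- fit_config(chains = 2, warmup_draws = 400, sampling_draws = 500, seed = 1,
                   prior_spec = prior, u2_refresh = 3)
  cal <- calibration_study(cfg, n_replicates = 20, seed = 77, joint_config = jc,
                           truth_mode = "prior")
  p_per <- vapply(split(cal$results$rank, cal$results$parameter),
                  function(x) rank_uniformity_test(x)$p.value, numeric(1))
  ## family-wise alpha = 0.01 across all sampled parameters
  expect_true(all(p_per > 0.01 / length(p_per)))
  expect_gt(rank_uniformity_test(cal$results$rank)$p.value, 0.01)
  ## an unfitted prior for the strict mode is rejected
  expect_error(calibration_study(cfg, 2, joint_config = fit_config(seed = 1),
                                 truth_mode = "prior"),
               class = "jmels_input_error")
})

test_that("single-shared-effect fits are confounded by correlated random effects", {
  ## location and log-scale effects strongly positively correlated; the
  ## location effect on the outcome is positive and the log-scale effect
  ## negative. Entering log-scale alone absorbs the omitted location effect,
  ## distorting the loading upward relative to the all-included fit.
  spec <- tiny_spec()
  p <- default_true_params(spec)
  p2 <- mels_params(beta = p$beta, alpha = p$alpha, gamma = p$gamma,
                    loadings = c(location = 0.04, slope = 0.01, log_scale = -0.3),
                    sd_u = c(5.39, 0.65, 0.42), cor_u = c(-0.09, 0.8, -0.05),
                    sigma_u3 = 0.19, sigma_eps = 5.61)
  cfg <- mels_generator_config(n_individuals = 250, spec = spec,
                               true_params = p2, seed = 55)
  sim <- simulate_mels(cfg)
  fc <- fit_config(chains = 2, warmup_draws = 400, sampling_draws = 400, seed = 4,
                   u2_refresh = 3)
  fv <- suppressWarnings(fit_variants(sim$data, spec,
                     variants = list(log_scale = "log_scale",
                                     all = c("location", "slope", "log_scale")),
                     config = fc))
  tab <- fv$table
  only <- tab$mean[tab$variant == "log_scale" & tab$effect == "log_scale"]
  full <- tab$mean[tab$variant == "all" & tab$effect == "log_scale"]
  expect_gt(only, full)       # omitted positive location effect inflates it
  expect_equal(nrow(tab), 1 + 3)
})
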