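# Synthetic data from the exact generative process of the joint model, with a
# study design emulating a longitudinal birth cohort: six clinics between ages
# ~7.5 and ~15.5 years, two blood-pressure readings per clinic (one clinic
# storing only their mean), covariate-dependent mean and log-variance, per-
# clinic attendance thinning, and a distal outcome (log LVMI) at ~17.7 years.

#' Default model specification of the generator
#'
#' Mean function: linear spline in age (knot 12) with sex interactions, log
#' body weight, height, and maternal covariates (age at delivery, parity,
#' education). Scale function: age, sex, log weight, height. Outcome function:
#' age at outcome, sex, weight at outcome.
#'
#' @param levels 2 or 3.
#' @param shared_effects Shared random effects (default all three).
#' @return A `mels_spec`.
#' @export
default_spec <- function(levels = 3,
                         shared_effects = c("location", "slope", "log_scale")) {
  mels_spec(
    mean_terms = c("s1", "s2", "female", "female:s1", "female:s2",
                   "log_weight", "height", "mat_age", "parity",
                   "edu_vocational", "edu_olevel", "edu_alevel", "edu_degree"),
    scale_terms = c("age", "female", "log_weight", "height"),
    outcome_terms = c("age_outcome", "female", "weight_outcome"),
    knot = 12, shared_effects = shared_effects, levels = levels)
}

#' Default true parameters of the generator
#'
#' A documented parameter set on the centered-covariate scale: systolic blood
#' pressure in mm Hg with a mean of ~108 at the mean age, spline slopes
#' -0.56/3.83 mm Hg per year below/above the knot, individual SDs 5.39
#' (location), 0.65 (slope) and 0.42 (log within-individual variance),
#' correlations (-0.09, 0.50, -0.05), within-clinic SD 5.61; the log-variance
#' function has intercept 3.13 and percentage effects of age (+10.8%/year),
#' female sex (+20.06%), weight (+5.24% per 10% weight increase) and height
#' (-0.24%/cm), stored as log-scale coefficients; the log-outcome carries
#' loadings 0.59%/mm Hg (location), 3.58%/mm Hg/year (slope) and -0.78% per
#' 10% variance increase (log-scale), with residual SD 0.19.
#'
#' @param spec A `mels_spec` whose term lists select which coefficients are
#'   needed (defaults to [default_spec()]).
#' @return A `mels_params` object aligned with `spec`.
#' @export
default_true_params <- function(spec = default_spec()) {
  pct <- function(p) log(1 + p / 100)             # invert (exp(b)-1)*100
  pct10 <- function(p) log(1 + p / 100) / log(1.10) # invert (1.10^b-1)*100
  beta_all <- c(`(Intercept)` = 108.23, s1 = -0.56, s2 = 3.83, female = -0.22,
                `female:s1` = -0.17, `female:s2` = -1.25,
                log_weight = 16.56, height = 0.06, mat_age = 0.01, parity = -0.17,
                edu_vocational = -0.04, edu_olevel = 0.05, edu_alevel = -0.64,
                edu_degree = -1.39)
  alpha_all <- c(`(Intercept)` = 3.13, age = pct(10.80), female = pct(20.06),
                 log_weight = pct10(5.24), height = pct(-0.24))
  gamma_all <- c(`(Intercept)` = 3.32, age_outcome = pct(-1.94),
                 female = pct(-4.95), weight_outcome = pct(0.70))
  loadings_all <- c(location = pct(0.59), slope = pct(3.58), log_scale = pct10(-0.78))

  pick <- function(all, terms, what) {
    need <- c("(Intercept)", terms)
    miss <- setdiff(need, names(all))
    if (length(miss))
      stop_jmels("no default true value for ", what, " term(s): ",
                 paste(miss, collapse = ", "), class = "jmels_contract_error")
    all[need]
  }
  mels_params(beta = pick(beta_all, spec$mean_terms, "mean"),
              alpha = pick(alpha_all, spec$scale_terms, "scale"),
              gamma = pick(gamma_all, spec$outcome_terms, "outcome"),
              loadings = loadings_all[spec$shared_effects],
              sd_u = c(5.39, 0.65, 0.42), cor_u = c(-0.09, 0.50, -0.05),
              sigma_u3 = 0.19,
              sigma_eps = if (spec$levels == 3) 5.61 else NA_real_)
}

#' Generator configuration
#'
#' Defaults reproduce the cohort design: clinics near ages 7.5, 9.5, 10.5,
#' 11.5, 13 and 15.5 years with within-clinic age jitter SD 0.25 y; two
#' readings per clinic, with the 10.5-year clinic storing only their mean
#' (recorded with `n_pooled = 2`); independent per-clinic attendance with
#' probabilities matched to the printed per-clinic sample sizes; a distal
#' outcome at age ~17.7 y. Covariates: sex ~ Bernoulli(0.549) (female = 1),
#' log weight and height growing linearly in age with individual random
#' intercepts, maternal age at delivery ~ N(29.5, 4.6^2), parity ~
#' Poisson(0.7), and maternal education sampled from the cohort proportions.
#'
#' @param n_individuals Number of individuals J.
#' @param clinic_ages Mean ages of the clinics (strictly increasing).
#' @param age_jitter_sd SD of individual age around the clinic mean (years).
#' @param reps_per_clinic Readings per clinic (scalar or per-clinic vector).
#' @param pool_clinic Index of the clinic whose readings are stored as their
#'   mean (`NA` for none). Default 3 (the ~10.5-year clinic).
#' @param attendance Per-clinic attendance probabilities.
#' @param outcome_age Mean age at the outcome measurement.
#' @param outcome_missing_rate Probability an individual's outcome is missing
#'   (attrition never removes the outcome row itself).
#' @param true_params A `mels_params` (default [default_true_params()]).
#' @param spec The generating `mels_spec` (default [default_spec()]).
#' @param covariate_model Named list of covariate-distribution settings (see
#'   defaults in the function definition).
#' @param seed Integer seed.
#' @return An object of class `mels_generator_config`.
#' @export
mels_generator_config <- function(n_individuals = 2000,
                                  clinic_ages = c(7.5, 9.5, 10.5, 11.5, 13, 15.5),
                                  age_jitter_sd = 0.25,
                                  reps_per_clinic = 2,
                                  pool_clinic = 3,
                                  attendance = c(0.885, 0.908, 0.882, 0.902, 0.887, 0.851),
                                  outcome_age = 17.7,
                                  outcome_missing_rate = 0,
                                  true_params = NULL,
                                  spec = default_spec(),
                                  covariate_model = list(),
                                  seed = 1) {
  if (n_individuals < 1) stop_jmels("n_individuals must be >= 1", class = "jmels_contract_error")
  if (is.unsorted(clinic_ages, strictly = TRUE))
    stop_jmels("clinic_ages must be strictly increasing", class = "jmels_contract_error")
  if (any(attendance < 0 | attendance > 1))
    stop_jmels("attendance probabilities must be in [0, 1]", class = "jmels_contract_error")
  if (length(attendance) != length(clinic_ages))
    stop_jmels("attendance must have one probability per clinic", class = "jmels_contract_error")
  if (outcome_missing_rate < 0 || outcome_missing_rate > 1)
    stop_jmels("outcome_missing_rate must be in [0, 1]", class = "jmels_contract_error")
  reps <- rep(reps_per_clinic, length.out = length(clinic_ages))
  if (any(reps < 1)) stop_jmels("reps_per_clinic must be >= 1", class = "jmels_contract_error")
  cm <- utils::modifyList(list(
    sex_p = 0.549,
    log_weight = list(intercept = 3.66, slope = 0.085, ref_age = 11.3,
                      sd_individual = 0.18, sd_visit = 0.05),
    height = list(intercept = 145, slope = 5.5, ref_age = 11.3,
                  sd_individual = 7, sd_visit = 1),
    outcome_age_sd = 0.35,
    mat_age = c(mean = 29.5, sd = 4.6),
    parity_lambda = 0.7,
    edu_p = c(cse_none = 0.115, vocational = 0.080, olevel = 0.334,
              alevel = 0.270, degree = 0.201)
  ), covariate_model)
  structure(list(n_individuals = as.integer(n_individuals), clinic_ages = clinic_ages,
                 age_jitter_sd = age_jitter_sd, reps_per_clinic = reps,
                 pool_clinic = pool_clinic, attendance = attendance,
                 outcome_age = outcome_age, outcome_missing_rate = outcome_missing_rate,
                 true_params = true_params %||% default_true_params(spec),
                 spec = spec, covariate_model = cm, seed = as.integer(seed)),
            class = "mels_generator_config")
}

#' Simulate a dataset from the generative model
#'
#' Draws individual random effects from `MVN(0, Sigma_u)`, computes the
#' within-individual variance per clinic visit through the log-linear scale
#' function, draws the clinic-level errors and within-clinic measurement
#' errors, assembles the exposure readings and the distal outcome, and applies
#' attendance thinning. Covariates are generated first and the fixed parts are
#' evaluated through the package's own design-building code on the realized
#' sample (so the true parameters live on exactly the centered scale the model
#' is fitted on). Returns the three observable tables plus the latent truth.
#'
#' @param config A `mels_generator_config`.
#' @return An object of class `mels_sim`: list with `data` (a `mels_data`),
#'   `design` (the design built under the generating spec), `truth`
#'   (random effects `u`, outcome residuals `u3`, clinic errors `e`,
#'   within-individual variances `s2e`), and `config`.
#' @export
simulate_mels <- function(config) {
  stopifnot(inherits(config, "mels_generator_config"))
  p <- config$true_params
  ev <- eigen(p$Sigma_u, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop_jmels("true Sigma_u is not positive semi-definite",
               class = "jmels_definiteness_error")
  set.seed(config$seed)
  J <- config$n_individuals
  C <- length(config$clinic_ages)
  cm <- config$covariate_model

  ## ---- individuals and covariates ----------------------------------------
  female <- rbinom(J, 1, cm$sex_p)
  mat_age <- rnorm(J, cm$mat_age["mean"], cm$mat_age["sd"])
  parity <- rpois(J, cm$parity_lambda)
  edu <- sample(names(cm$edu_p), J, replace = TRUE, prob = cm$edu_p)
  a_w <- rnorm(J, 0, cm$log_weight$sd_individual)   # weight growth intercepts
  a_h <- rnorm(J, 0, cm$height$sd_individual)

  ## ---- attendance ---------------------------------------------------------
  attend <- matrix(rbinom(J * C, 1, rep(config$attendance, each = J)), J, C) == 1
  has_any <- rowSums(attend) > 0
  if (any(!has_any)) {       # individuals with no clinic visits never enter the study
    attend <- attend[has_any, , drop = FALSE]
    female <- female[has_any]; mat_age <- mat_age[has_any]; parity <- parity[has_any]
    edu <- edu[has_any]; a_w <- a_w[has_any]; a_h <- a_h[has_any]
  }
  J <- nrow(attend)
  id <- sprintf("id%05d", seq_len(J))

  ## ---- clinic table -------------------------------------------------------
  vis <- which(attend, arr.ind = TRUE)
  vis <- vis[order(vis[, 1], vis[, 2]), , drop = FALSE]
  jj <- vis[, 1]; ci <- vis[, 2]
  age <- config$clinic_ages[ci] + rnorm(nrow(vis), 0, config$age_jitter_sd)
  lw <- cm$log_weight$intercept + cm$log_weight$slope * (age - cm$log_weight$ref_age) +
    a_w[jj] + rnorm(nrow(vis), 0, cm$log_weight$sd_visit)
  ht <- cm$height$intercept + cm$height$slope * (age - cm$height$ref_age) +
    a_h[jj] + rnorm(nrow(vis), 0, cm$height$sd_visit)
  clinics <- data.frame(individual_id = id[jj], clinic_id = ci, age = age,
                        weight = exp(lw), height = ht)

  ## ---- individual table ---------------------------------------------------
  age_out <- rnorm(J, config$outcome_age, cm$outcome_age_sd)
  lw_out <- cm$log_weight$intercept + cm$log_weight$slope * (age_out - cm$log_weight$ref_age) +
    a_w + rnorm(J, 0, cm$log_weight$sd_visit)
  individuals <- data.frame(individual_id = id, female = female,
                            age_outcome = age_out, weight_outcome = exp(lw_out),
                            mat_age = mat_age, parity = parity,
                            edu_vocational = as.integer(edu == "vocational"),
                            edu_olevel = as.integer(edu == "olevel"),
                            edu_alevel = as.integer(edu == "alevel"),
                            edu_degree = as.integer(edu == "degree"),
                            outcome = 1)   # placeholder, filled below

  ## ---- measurement skeleton ----------------------------------------------
  reps <- config$reps_per_clinic[ci]
  pooled <- !is.na(config$pool_clinic) & ci == config$pool_clinic
  n_rows <- ifelse(pooled, 1L, reps)
  ridx <- rep(seq_len(nrow(vis)), n_rows)
  occ <- sequence(n_rows)
  measurements <- data.frame(individual_id = id[jj][ridx], clinic_id = ci[ridx],
                             occasion = occ, value = 0,
                             n_pooled = ifelse(pooled[ridx], reps[ridx], 1L))

  ## ---- design under the generating spec (defines the centered scale) ------
  dat0 <- mels_data(measurements, clinics, individuals)
  design <- build_design(dat0, config$spec)

  ## ---- latent draws and responses -----------------------------------------
  u <- rmvn(J, c(0, 0, 0), p$Sigma_u + diag(1e-12, 3))
  if (min(ev) <= 0) { # degenerate components: project exactly to zero variance
    zero <- diag(p$Sigma_u) == 0
    u[, zero] <- 0
  }
  effects <- mels_effects(u)
  sv <- log_within_variance(design, p, effects)
  e <- rnorm(nrow(design$X_mean), 0, sqrt(sv$var))
  mu_v <- mean_predictor(design, p, effects)
  mvisit <- design$meas_visit
  se <- if (is.na(p$sigma_eps)) 0 else p$sigma_eps
  eps <- rnorm(length(mvisit), 0, se / sqrt(design$w_pooled)) # pooled mean of k readings
  y1 <- mu_v[mvisit] + e[mvisit] + eps
  u3 <- rnorm(J, 0, p$sigma_u3)
  eta <- outcome_predictor(design, p, effects)
  y2 <- eta + u3
  if (config$outcome_missing_rate > 0)
    y2[runif(J) < config$outcome_missing_rate] <- NA_real_

  ## write the responses back into the observable tables (original row order)
  ord_m <- order(measurements$individual_id, measurements$clinic_id, measurements$occasion)
  measurements$value[ord_m] <- y1
  out_raw <- if (config$spec$log_outcome) exp(y2) else y2
  individuals$outcome <- out_raw[match(individuals$individual_id, design$individual_ids)]

  data <- mels_data(measurements, clinics, individuals)
  design <- build_design(data, config$spec, require_outcome = FALSE)

  truth <- list(u = effects, u3 = u3, e = e, s2e = sv$var, eps = eps,
                individual_ids = design$individual_ids,
                visit_keys = design$visit_keys)
  structure(list(data = data, design = design, truth = truth, config = config),
            class = "mels_sim")
}

#' @export
print.mels_sim <- function(x, ...) {
  v <- x$data$validation
  cat("Synthetic joint-model dataset:", v$n_individuals, "individuals,",
      v$n_clinic_visits, "clinic visits,", v$n_measurements, "measurements",
      "(seed", x$config$seed, ")\n")
  invisible(x)
}

#' Closed-form vs empirical moment check of the generator
#'
#' Within each clinic (age band), compares the empirical variance of the
#' measurement residuals around the true fixed part against the closed-form
#' marginal variance
#' \deqn{\sigma^2_{u0} + z^2 \sigma^2_{u1} + 2 z \sigma_{u01} +
#'       \exp(x_s'\alpha + \sigma^2_{u2}/2) + \sigma^2_\epsilon / n_{pooled},}
#' averaged over the band's covariates (the exponential term is the lognormal
#' mean of the within-individual variance), and the empirical mean of the
#' measurements against the fixed part.
#'
#' @param sim A `mels_sim` object.
#' @return Data frame per clinic band: empirical and theoretical variance,
#'   their relative error, and the relative error of the mean.
#' @export
moment_check <- function(sim) {
  stopifnot(inherits(sim, "mels_sim"))
  design <- sim$design
  p <- sim$config$true_params
  zero_u <- mels_effects(matrix(0, nrow(design$X_outcome), 3))
  fix_mu <- mean_predictor(design, p, zero_u)
  fix_lv <- drop(design$X_scale %*% p$alpha)
  s2u <- diag(p$Sigma_u)
  z <- design$z_age
  se2 <- if (is.na(p$sigma_eps)) 0 else p$sigma_eps^2
  mvis <- design$meas_visit
  theo_m <- s2u[1] + z[mvis]^2 * s2u[2] + 2 * z[mvis] * p$Sigma_u[1, 2] +
    exp(fix_lv[mvis] + s2u[3] / 2) + se2 / design$w_pooled
  resid <- design$y1 - fix_mu[mvis]
  band <- design$clinic_ids[mvis]
  out <- do.call(rbind, lapply(sort(unique(band)), function(b) {
    i <- band == b
    emp_var <- stats::var(resid[i])
    th_var <- mean(theo_m[i])
    data.frame(band = b, n = sum(i),
               empirical_var = emp_var, theoretical_var = th_var,
               rel_error_var = (emp_var - th_var) / th_var,
               empirical_mean = mean(design$y1[i]),
               rel_error_mean = mean(resid[i]) / mean(design$y1[i]))
  }))
  rownames(out) <- NULL
  out
}
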