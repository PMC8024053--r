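# The two-stage procedure the joint model replaces: per-individual summaries
# first (OLS intercept and slope on clinic means, log sample residual
# variance), then an outcome regression on those summaries. Stage-one
# estimates carry sampling error that stage two ignores, which biases
# (typically attenuates) the outcome coefficients; the joint model integrates
# over that uncertainty instead.

STAGE1_VAR_FLOOR <- 1e-8

#' Stage one: per-individual trajectory and variability summaries
#'
#' For every individual with at least `min_visits` clinic visits, ordinary
#' least squares of the clinic-mean exposure on centered age gives an
#' intercept (at centered age 0) and slope; the log of the unbiased residual
#' variance estimates the individual's log within-individual variance.
#' Exact-fit individuals (residual variance 0) are floored at `1e-8` before
#' the log. Individuals with fewer visits are flagged and excluded from
#' stage two.
#'
#' @param data A `mels_data` object.
#' @param center Age centering constant (default: grand mean of clinic ages,
#'   matching the design-matrix convention).
#' @param min_visits Minimum clinic visits (default 3; below that the line
#'   leaves no residual degrees of freedom).
#' @return Data frame: `individual_id`, `intercept`, `slope`,
#'   `log_resid_var`, `n_visits`, `flagged`.
#' @export
stage_one <- function(data, center = NULL, min_visits = 3) {
  stopifnot(inherits(data, "mels_data"))
  m <- data$measurements
  cl <- data$clinics
  vkey <- paste(cl$individual_id, cl$clinic_id)
  mkey <- match(paste(m$individual_id, m$clinic_id), vkey)
  V <- nrow(cl)
  W <- rowsum_vec(m$n_pooled, mkey, V)
  ybar <- rowsum_vec(m$n_pooled * m$value, mkey, V) / W
  center <- center %||% mean(cl$age)
  z <- cl$age - center

  ids <- data$individuals$individual_id
  ji <- match(cl$individual_id, ids)
  J <- length(ids)
  n <- tabulate(ji, J)
  Sx <- rowsum_vec(z, ji, J); Sy <- rowsum_vec(ybar, ji, J)
  Sxx <- rowsum_vec(z^2, ji, J); Sxy <- rowsum_vec(z * ybar, ji, J)
  Syy <- rowsum_vec(ybar^2, ji, J)
  Sxx_c <- Sxx - Sx^2 / pmax(n, 1)
  Sxy_c <- Sxy - Sx * Sy / pmax(n, 1)
  Syy_c <- Syy - Sy^2 / pmax(n, 1)
  slope <- ifelse(Sxx_c > 0, Sxy_c / Sxx_c, NA_real_)
  intercept <- Sy / pmax(n, 1) - slope * Sx / pmax(n, 1)
  rss <- pmax(Syy_c - slope^2 * Sxx_c, 0)
  resid_var <- ifelse(n > 2, rss / (n - 2), NA_real_)
  flagged <- n < min_visits | !is.finite(slope)
  log_resid_var <- log(pmax(resid_var, STAGE1_VAR_FLOOR))
  ## OLS sampling variances of the summaries (used to noise-correct
  ## between-individual variance guesses)
  zbar <- Sx / pmax(n, 1)
  se2_intercept <- resid_var * (1 / pmax(n, 1) + zbar^2 / pmax(Sxx_c, 1e-12))
  se2_slope <- resid_var / pmax(Sxx_c, 1e-12)
  out <- data.frame(individual_id = ids, intercept = intercept, slope = slope,
                    log_resid_var = log_resid_var, n_visits = n, flagged = flagged,
                    se2_intercept = se2_intercept, se2_slope = se2_slope)
  out$intercept[flagged] <- NA_real_
  out$slope[flagged] <- NA_real_
  out$log_resid_var[flagged] <- NA_real_
  attr(out, "center") <- center
  out
}

#' Stage two: outcome regression on stage-one summaries
#'
#' Ordinary least squares of the (log) outcome on the grand-mean centered
#' stage-one summaries plus the outcome-model covariates. The coefficients of
#' the centered intercept, slope and log residual variance are the two-stage
#' analogues of the three shared-random-effect loadings.
#'
#' @param summaries Output of [stage_one()].
#' @param data A `mels_data` object.
#' @param spec A `mels_spec` (supplies the outcome covariate terms).
#' @return An object of class `mels_two_stage`: coefficient table with
#'   standard errors, loadings aligned to `(location, slope, log_scale)`, and
#'   the number of individuals used.
#' @export
stage_two <- function(summaries, data, spec) {
  design <- build_design(data, spec)
  idx <- match(design$individual_ids, summaries$individual_id)
  s <- summaries[idx, ]
  ok <- !s$flagged & !is.na(design$y2)
  if (sum(ok) < 10)
    stop_jmels("stage two needs >= 10 individuals with complete stage-one summaries (got ",
               sum(ok), ")", class = "jmels_precondition_error")
  S <- cbind(location = s$intercept[ok] - mean(s$intercept[ok]),
             slope = s$slope[ok] - mean(s$slope[ok]),
             log_scale = s$log_resid_var[ok] - mean(s$log_resid_var[ok]))
  X <- cbind(design$X_outcome[ok, , drop = FALSE], S)
  y <- design$y2[ok]
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop_jmels("stage-two design is rank deficient (collinear summaries)",
               class = "jmels_rank_error")
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(XtXinv) * sigma2)
  coef_tab <- data.frame(term = colnames(X), estimate = fit$coefficients,
                         se = se, row.names = NULL)
  loadings <- fit$coefficients[c("location", "slope", "log_scale")]
  structure(list(coefficients = coef_tab, loadings = loadings,
                 loading_se = se[match(c("location", "slope", "log_scale"),
                                       colnames(X))],
                 n_used = sum(ok), sigma = sqrt(sigma2)),
            class = "mels_two_stage")
}

#' @export
print.mels_two_stage <- function(x, ...) {
  cat("Two-stage outcome regression on", x$n_used, "individuals\n")
  print(transform(x$coefficients, estimate = signif(estimate, 4), se = signif(se, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Convenience wrapper: both stages
#'
#' @inheritParams stage_two
#' @param min_visits Passed to [stage_one()].
#' @return A `mels_two_stage` object with the stage-one table attached.
#' @export
fit_two_stage <- function(data, spec, min_visits = 3) {
  s1 <- stage_one(data, min_visits = min_visits)
  out <- stage_two(s1, data, spec)
  out$stage_one <- s1
  out
}

#' Replicated bias comparison: joint model vs two-stage
#'
#' Simulates `n_replicates` datasets from a generator configuration, fits both
#' the joint model and the two-stage procedure to each, and tabulates the
#' shared-effect (loading) estimates against the generating truth. With few
#' visits per individual and non-zero within-clinic error the two-stage
#' log-scale loading is attenuated toward zero by the sampling noise in the
#' stage-one variance estimates, while the joint estimator is approximately
#' unbiased.
#'
#' @param generator_config A `mels_generator_config`.
#' @param n_replicates Number of simulate-fit replicates (>= 1).
#' @param seed Master seed (per-replicate seeds derived deterministically).
#' @param joint_config A `mels_fit_config` for the joint fits.
#' @return A list with `results` (one row per replicate x method x effect:
#'   estimate, reported SE, truth) and `summary` (per method x effect: mean
#'   bias, its Monte-Carlo SE, RMSE, mean reported SE, replicate SD).
#' @export
bias_experiment <- function(generator_config, n_replicates, seed = 1,
                            joint_config = fit_config(chains = 1, warmup_draws = 300,
                                                      sampling_draws = 300, seed = 1)) {
  if (n_replicates < 1)
    stop_jmels("n_replicates must be >= 1", class = "jmels_input_error")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_replicates)
  spec <- generator_config$spec
  truth <- generator_config$true_params$loadings
  rows <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- generator_config
    cfg$seed <- rep_seeds[r]
    sim <- simulate_mels(cfg)
    jc <- joint_config
    jc$seed <- rep_seeds[r]
    joint <- suppressWarnings(fit_mels(sim$data, spec, jc, design = sim$design))
    ts <- fit_two_stage(sim$data, spec)
    for (eff in spec$shared_effects) {
      pn <- paste0("gamma[", eff, "]")
      js <- joint$summary[joint$summary$parameter == pn, ]
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, method = c("joint", "two_stage"), effect = eff,
        estimate = c(js$mean, unname(ts$loadings[eff])),
        se = c(js$sd, unname(ts$loading_se[match(eff, c("location", "slope", "log_scale"))])),
        truth = unname(truth[eff]))
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(results, list(results$method, results$effect)),
    function(d) data.frame(method = d$method[1], effect = d$effect[1],
                           mean_bias = mean(d$estimate - d$truth),
                           bias_mcse = stats::sd(d$estimate) / sqrt(nrow(d)),
                           rmse = sqrt(mean((d$estimate - d$truth)^2)),
                           mean_reported_se = mean(d$se),
                           replicate_sd = stats::sd(d$estimate))))
  rownames(agg) <- NULL
  list(results = results, summary = agg)
}
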