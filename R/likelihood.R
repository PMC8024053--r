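# Exact probability model: linear predictors, log-variance function, and the
# complete-data log density with the clinic-level error e_ij marginalized
# analytically. Each clinic visit's vector of measurements is multivariate
# normal with a compound-symmetry covariance
#   sigma2_e(visit) * J + diag(sigma_eps^2 / n_pooled),
# evaluated via the Sherman-Morrison identity so no matrix is ever formed.

LOGVAR_CLIP <- 30

check_dims <- function(design, params, effects) {
  if (length(params$beta) != ncol(design$X_mean))
    stop_jmels("beta has length ", length(params$beta), " but X_mean has ",
               ncol(design$X_mean), " columns", class = "jmels_contract_error")
  if (length(params$alpha) != ncol(design$X_scale))
    stop_jmels("alpha has length ", length(params$alpha), " but X_scale has ",
               ncol(design$X_scale), " columns", class = "jmels_contract_error")
  if (length(params$gamma) != ncol(design$X_outcome))
    stop_jmels("gamma has length ", length(params$gamma), " but X_outcome has ",
               ncol(design$X_outcome), " columns", class = "jmels_contract_error")
  if (!is.null(effects) && nrow(effects) != nrow(design$X_outcome))
    stop_jmels("random effects have ", nrow(effects), " rows but the design has ",
               nrow(design$X_outcome), " individuals", class = "jmels_contract_error")
  invisible(TRUE)
}

#' Mean of the exposure at clinic visits
#'
#' The location linear predictor: fixed part `X_mean %*% beta` plus the
#' individual location effect and the individual slope effect times centered
#' age, for the requested clinic visits.
#'
#' @param design A `mels_design` object.
#' @param params A `mels_params` object.
#' @param effects A J x 3 matrix of individual random effects `(u0, u1, u2)`.
#' @param visits Integer indices of clinic visits (default: all).
#' @return Numeric vector of means (exposure units, e.g. mm Hg).
#' @export
mean_predictor <- function(design, params, effects, visits = NULL) {
  check_dims(design, params, effects)
  visits <- visits %||% seq_len(nrow(design$X_mean))
  j <- design$visit_individual[visits]
  unname(drop(design$X_mean[visits, , drop = FALSE] %*% params$beta) +
           effects[j, 1] + effects[j, 2] * design$z_age[visits])
}

#' Within-individual (visit-to-visit) variance at clinic visits
#'
#' The scale linear predictor on the log-variance scale,
#' `X_scale %*% alpha + u2`, and its exponential. The log link guarantees a
#' positive variance for any inputs. Log variances are clipped to
#' `[-30, 30]` (with a warning) to guard density evaluations against
#' overflow during sampling.
#'
#' @inheritParams mean_predictor
#' @return A list with elements `log_var` and `var` (vectors over visits).
#' @export
log_within_variance <- function(design, params, effects, visits = NULL) {
  check_dims(design, params, effects)
  visits <- visits %||% seq_len(nrow(design$X_scale))
  j <- design$visit_individual[visits]
  lv <- unname(drop(design$X_scale[visits, , drop = FALSE] %*% params$alpha) +
               effects[j, 3])
  if (any(abs(lv) > LOGVAR_CLIP)) {
    warning("log within-individual variance clipped to [-", LOGVAR_CLIP, ", ",
            LOGVAR_CLIP, "]")
    lv <- pmin(pmax(lv, -LOGVAR_CLIP), LOGVAR_CLIP)
  }
  list(log_var = lv, var = exp(lv))
}

#' Mean of the distal outcome
#'
#' The outcome linear predictor: covariate part `X_outcome %*% gamma` plus the
#' shared-random-effect part `sum_k loading_k * u_kj` over the effects the
#' specification shares into the outcome model.
#'
#' @inheritParams mean_predictor
#' @param spec The `mels_spec` (defaults to the one stored in `design`).
#' @param individuals Integer indices of individuals (default: all).
#' @return Numeric vector of outcome means (log-outcome scale).
#' @export
outcome_predictor <- function(design, params, effects, spec = design$spec,
                              individuals = NULL) {
  check_dims(design, params, effects)
  active <- spec$shared_effects
  extra <- setdiff(names(params$loadings), active)
  if (length(extra))
    stop_jmels("loading(s) supplied for inactive shared effect(s): ",
               paste(extra, collapse = ", "), class = "jmels_contract_error")
  missing_l <- setdiff(active, names(params$loadings))
  if (length(missing_l))
    stop_jmels("missing loading(s) for shared effect(s): ",
               paste(missing_l, collapse = ", "), class = "jmels_contract_error")
  individuals <- individuals %||% seq_len(nrow(design$X_outcome))
  eta <- drop(design$X_outcome[individuals, , drop = FALSE] %*% params$gamma)
  ucol <- c(location = 1L, slope = 2L, log_scale = 3L)
  for (eff in active)
    eta <- eta + params$loadings[[eff]] * effects[individuals, ucol[[eff]]]
  unname(eta)
}

## Per-visit marginal (over e) log density of the measurement vectors,
## returned per visit. Compound symmetry via Sherman-Morrison.
visit_logdensity <- function(design, params, effects, s2e = NULL) {
  if (is.null(s2e)) s2e <- log_within_variance(design, params, effects)$var
  mu <- mean_predictor(design, params, effects)
  v <- design$meas_visit
  r <- design$y1 - mu[v]
  V <- nrow(design$X_mean)
  if (design$spec$levels == 2) {
    return(-0.5 * (log(2 * pi) + log(s2e) + r^2 / s2e))
  }
  if (params$sigma_eps == 0) {
    n_v <- tabulate(v, nbins = V)
    if (any(n_v > 1))
      stop_jmels("sigma_eps = 0 requires a single measurement per clinic visit",
                 class = "jmels_contract_error")
    return(-0.5 * (log(2 * pi) + log(s2e) + r^2 / s2e))
  }
  d <- params$sigma_eps^2 / design$w_pooled      # per-measurement error variance
  sum_inv <- rowsum_vec(1 / d, v, V)
  sum_r <- rowsum_vec(r / d, v, V)
  sum_r2 <- rowsum_vec(r^2 / d, v, V)
  sum_logd <- rowsum_vec(log(d), v, V)
  n_v <- tabulate(v, nbins = V)
  denom <- 1 + s2e * sum_inv
  logdet <- sum_logd + log(denom)
  quad <- sum_r2 - s2e * sum_r^2 / denom
  -0.5 * (n_v * log(2 * pi) + logdet + quad)
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  tmp <- rowsum(x, idx)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

## Log MVN density, generic (used for the random-effect prior term).
dmvn_log <- function(X, Sigma) {
  L <- tryCatch(chol(Sigma), error = function(e)
    stop_jmels("covariance not positive definite", class = "jmels_definiteness_error"))
  p <- ncol(Sigma)
  z <- backsolve(L, t(X), transpose = TRUE)
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(L)))) * rep(1, nrow(X)) -
    0.5 * colSums(z^2)
}

## Outcome log density per individual (0 where the outcome is missing).
outcome_logdensity <- function(design, params, effects, spec = design$spec) {
  out <- numeric(nrow(design$X_outcome))
  obs <- which(!is.na(design$y2))
  if (!length(obs)) return(out)
  eta <- outcome_predictor(design, params, effects, spec, individuals = obs)
  out[obs] <- dnorm(design$y2[obs], eta, params$sigma_u3, log = TRUE)
  out
}

#' Complete-data log density of the joint model
#'
#' The log density of all measurements (with the clinic-level error
#' marginalized analytically within each visit), the distal outcomes for the
#' individuals that have one, and the random effects, at fixed parameters and
#' random effects:
#' \deqn{\sum_v \log N(y_v; \mu_v 1, \sigma^2_{e,v} J + \mathrm{diag}(\sigma^2_\epsilon / n_{pooled})) +
#'       \sum_j \log N(u_j; 0, \Sigma_u) + \sum_j \log N(y_{2j}; \eta_j, \sigma^2_{u3}).}
#'
#' @inheritParams mean_predictor
#' @param spec The `mels_spec` (defaults to the one stored in `design`).
#' @return A single number (log density).
#' @export
complete_data_loglik <- function(design, params, effects, spec = design$spec) {
  check_dims(design, params, effects)
  sum(visit_logdensity(design, params, effects)) +
    sum(dmvn_log(unclass(effects)[, 1:3, drop = FALSE], params$Sigma_u)) +
    sum(outcome_logdensity(design, params, effects, spec))
}

## Log likelihood contribution of one individual's visits + outcome at a grid
## of random-effect values. u is K x 3. Returns length-K vector.
individual_loglik_grid <- function(design, params, j, u, spec = design$spec) {
  vis <- which(design$visit_individual == j)
  K <- nrow(u)
  fix_mu <- drop(design$X_mean[vis, , drop = FALSE] %*% params$beta)
  fix_lv <- drop(design$X_scale[vis, , drop = FALSE] %*% params$alpha)
  z <- design$z_age[vis]
  ## V_j x K matrices of visit means and log variances across grid points
  mu <- outer(fix_mu, rep(1, K)) + outer(rep(1, length(vis)), u[, 1]) +
    outer(z, u[, 2])
  lv <- outer(fix_lv, rep(1, K)) + outer(rep(1, length(vis)), u[, 3])
  lv <- pmin(pmax(lv, -LOGVAR_CLIP), LOGVAR_CLIP)
  s2e <- exp(lv)
  ll <- numeric(K)
  for (i in seq_along(vis)) {
    m <- which(design$meas_visit == vis[i])
    y <- design$y1[m]
    if (design$spec$levels == 2 || params$sigma_eps == 0) {
      ll <- ll - 0.5 * (log(2 * pi) + lv[i, ] + (y - mu[i, ])^2 / s2e[i, ])
    } else {
      d <- params$sigma_eps^2 / design$w_pooled[m]
      r <- outer(y, rep(1, K)) - outer(rep(1, length(m)), mu[i, ])
      sum_inv <- sum(1 / d)
      denom <- 1 + s2e[i, ] * sum_inv
      quad <- colSums(r^2 / d) - s2e[i, ] * colSums(r / d)^2 / denom
      ll <- ll - 0.5 * (length(m) * log(2 * pi) + sum(log(d)) + log(denom) + quad)
    }
  }
  if (!is.na(design$y2[j])) {
    eta <- drop(design$X_outcome[j, , drop = FALSE] %*% params$gamma)
    ucol <- c(location = 1L, slope = 2L, log_scale = 3L)
    for (eff in spec$shared_effects) eta <- eta + params$loadings[[eff]] * u[, ucol[[eff]]]
    ll <- ll + dnorm(design$y2[j], eta, params$sigma_u3, log = TRUE)
  }
  ll
}

#' Brute-force marginal log likelihood by Gauss-Hermite quadrature
#'
#' Integrates the complete-data density over the three individual random
#' effects by tensor-product Gauss-Hermite quadrature after a Cholesky
#' rotation of `Sigma_u`, independently per individual. Cost is
#' `order^3` density evaluations per individual, so this is a testing oracle
#' for small instances, not a production estimator.
#'
#' @param design A `mels_design` object (small: roughly <= 10 individuals).
#' @param params A `mels_params` object.
#' @param order Quadrature order per dimension (>= 5 recommended; a warning is
#'   issued below 5).
#' @return The marginal log likelihood (sum over individuals).
#' @export
marginal_loglik_gh <- function(design, params, order = 25) {
  check_dims(design, params, effects = NULL)
  if (order < 5) warning("quadrature order < 5 is unreliable")
  gh <- pracma::gaussHermite(order)
  grid <- as.matrix(expand.grid(k1 = seq_len(order), k2 = seq_len(order),
                                k3 = seq_len(order)))
  x <- cbind(gh$x[grid[, 1]], gh$x[grid[, 2]], gh$x[grid[, 3]])
  logw <- log(gh$w[grid[, 1]]) + log(gh$w[grid[, 2]]) + log(gh$w[grid[, 3]])
  L <- t(chol(params$Sigma_u))
  u <- sqrt(2) * x %*% t(L)
  total <- 0
  for (j in seq_len(nrow(design$X_outcome))) {
    ll <- individual_loglik_grid(design, params, j, u)
    total <- total + logsumexp(logw + ll) - 1.5 * log(pi)
  }
  total
}
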