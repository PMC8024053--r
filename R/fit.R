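# Bayesian estimation of the joint location-scale model by a blocked
# Gibbs/adaptive-Metropolis sampler.
#
# The measurement likelihood is reduced, exactly, to per-visit sufficient
# statistics: the pooled-weighted visit mean ybar_v ~ N(mu_v, s2e_v + se^2/W_v)
# and the pooled within-visit sum of squares SS ~ se^2 * chisq(df). Updates:
#   (u0,u1) | .     exact bivariate normal draws (conditionally conjugate)
#   u2 | .          vectorized adaptive random-walk Metropolis
#   Sigma_u | u     exact conjugate inverse-Wishart block draw
#   beta | .        exact multivariate normal draw (weighted regression)
#   alpha | .       adaptive multivariate random-walk Metropolis
#   sigma_eps | .   adaptive scalar Metropolis on the log scale
#   (gamma, loadings) | .  exact multivariate normal draw
#   sigma_u3 | .    adaptive scalar Metropolis on the log scale
# plus translation moves along the intercept/random-effect mean ridges
# (beta0 vs u0, spline slopes vs u1, alpha0 vs u2), which decorrelate the
# fixed intercepts from the random-effect means under the centered
# parameterization. Proposal scales adapt during warmup only.

#' Configuration for the MCMC fit
#'
#' @param chains Number of chains (>= 2 recommended; a single chain triggers a
#'   warning because split-R-hat is then unreliable).
#' @param warmup_draws Iterations discarded as warmup (adaptation happens
#'   here and is frozen afterwards).
#' @param sampling_draws Retained iterations per chain.
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @param prior_spec Optional prior list as produced by [default_priors()];
#'   `NULL` means data-scaled weakly informative defaults.
#' @param thin Keep every `thin`-th draw.
#' @param u2_refresh Number of Metropolis refreshes of the log-scale random
#'   effects per iteration.
#' @return An object of class `mels_fit_config`.
#' @export
fit_config <- function(chains = 2, warmup_draws = 500, sampling_draws = 1000,
                       seed = 1, prior_spec = NULL, thin = 1, u2_refresh = 2) {
  if (chains < 1) stop_jmels("chains must be >= 1", class = "jmels_contract_error")
  if (chains < 2) warning("a single chain makes R-hat unreliable; use >= 2 chains")
  if (warmup_draws <= 0 || sampling_draws <= 0)
    stop_jmels("warmup_draws and sampling_draws must be > 0", class = "jmels_contract_error")
  structure(list(chains = as.integer(chains), warmup_draws = as.integer(warmup_draws),
                 sampling_draws = as.integer(sampling_draws), seed = as.integer(seed),
                 prior_spec = prior_spec, thin = as.integer(thin),
                 u2_refresh = as.integer(u2_refresh)),
            class = "mels_fit_config")
}

#' Data-scaled weakly informative priors
#'
#' Normal priors on all fixed effects, centered at zero except the three
#' intercepts (centered at crude empirical locations), with scales set from
#' the empirical SDs of the response and of each design column; half-normal
#' priors on `sigma_eps` and `sigma_u3`; an inverse-Wishart prior
#' (`Sigma_df = 4`, the smallest proper choice, with the scale matrix set so
#' the prior mode sits at noise-corrected two-stage moment estimates) on
#' `Sigma_u`, whose conjugacy gives an exact block update and whose density
#' vanishes at singular matrices, keeping the posterior off degenerate
#' zero-variance configurations.
#'
#' @param design A `mels_design` object.
#' @return A named list of prior means/scales understood by [fit_mels()].
#' @export
default_priors <- function(design) {
  y1 <- design$y1
  s_y1 <- max(stats::sd(y1), 1e-3)
  col_sd <- function(X) {
    s <- apply(X, 2, stats::sd)
    s[colnames(X) == "(Intercept)"] <- 1
    pmax(s, 1e-3)
  }
  y2 <- design$y2[!is.na(design$y2)]
  s_y2 <- if (length(y2) > 1) max(stats::sd(y2), 1e-3) else 1

  ## Crude per-individual moment estimates scale the Sigma_u prior/proposal.
  ## Stage-one variances overstate the random-effect variances by the OLS
  ## sampling noise (for the log residual variance, by trigamma(df/2), the
  ## variance of the log of a chi-square); subtract it, with floors.
  s1 <- stage_one(design$data, center = design$centers$age, min_visits = 3)
  ok <- !s1$flagged
  if (sum(ok) > 5) {
    v_int <- stats::var(s1$intercept[ok]) - mean(s1$se2_intercept[ok])
    v_slp <- stats::var(s1$slope[ok]) - mean(s1$se2_slope[ok])
    v_lsc <- stats::var(s1$log_resid_var[ok]) -
      mean(trigamma(pmax(s1$n_visits[ok] - 2, 1) / 2))
    v_int <- max(v_int, 0.05 * stats::var(s1$intercept[ok]), 0.1)
    v_slp <- max(v_slp, 0.05 * stats::var(s1$slope[ok]), 0.01)
    v_lsc <- max(v_lsc, 0.05 * stats::var(s1$log_resid_var[ok]), 0.02)
  } else {
    v_int <- s_y1^2; v_slp <- 1; v_lsc <- 1
  }
  Sg <- diag(c(v_int, v_slp, v_lsc))

  beta_mean <- rep(0, ncol(design$X_mean))
  beta_mean[1] <- mean(y1)
  gamma_mean <- rep(0, ncol(design$X_outcome))
  gamma_mean[1] <- if (length(y2)) mean(y2) else 0
  alpha_mean <- rep(0, ncol(design$X_scale))
  alpha_mean[1] <- log(max(stats::var(y1) / 2, 1e-3))

  list(beta_mean = beta_mean,
       beta_sd = 10 * s_y1 / col_sd(design$X_mean),
       alpha_mean = alpha_mean,
       alpha_sd = c(3, rep(2, ncol(design$X_scale) - 1)) / col_sd(design$X_scale),
       gamma_mean = gamma_mean,
       gamma_sd = 10 * s_y2 / col_sd(design$X_outcome),
       ## one SD of a latent effect may move the outcome by ~ one outcome SD
       ## (a diffuse loading prior lets the weakly identified latent scale
       ## trade off against the loading and creates a spurious inflation mode)
       loading_sd = s_y2 / sqrt(diag(Sg)),
       sigma_eps_scale = 2 * s_y1,
       sigma_u3_scale = 2 * s_y2,
       Sigma_df = 4,
       Sigma_scale = 8 * Sg)
}

## Robbins-Monro step for a log proposal scale.
adapt_scale <- function(log_sc, acc, target, iter) {
  log_sc + min(0.1, 2 / sqrt(iter)) * (acc - target)
}

run_one_chain <- function(prep, config, prior, chain_seed, chain_id) {
  set.seed(chain_seed)
  V <- prep$V; J <- prep$J
  Xm <- prep$Xm; Xs <- prep$Xs; Xo <- prep$Xo
  z <- prep$z; ji <- prep$ji
  ybar <- prep$ybar; W <- prep$W; SS <- prep$SS; df_ss <- prep$df_ss
  y2 <- prep$y2; obs <- prep$obs; n_obs <- sum(obs)
  levels3 <- prep$levels3
  act <- prep$active   # logical length 3: location, slope, log_scale shared
  pm <- ncol(Xm); ps <- ncol(Xs); po <- ncol(Xo)

  ## ---- initial values (jittered per chain) --------------------------------
  w_init <- 1 / pmax(stats::var(ybar), 1)
  beta <- tryCatch(qr.solve(Xm, ybar), error = function(e) prior$beta_mean)
  ## ill-conditioned initial regressions (e.g. near-constant columns) can
  ## produce wild coefficients: clamp inits to the prior scale
  beta <- pmin(pmax(beta, prior$beta_mean - prior$beta_sd),
               prior$beta_mean + prior$beta_sd)
  beta <- beta + rnorm(pm, 0, 0.05 * pmax(abs(beta), 0.1))
  ## alpha init: regress crude per-individual log residual variances on the
  ## per-individual mean scale design
  n_j <- pmax(tabulate(ji, J), 1)
  Dm <- rowsum(Xs, ji, reorder = TRUE)
  Dm_full <- matrix(0, J, ps)
  Dm_full[as.integer(rownames(Dm)), ] <- Dm / n_j[as.integer(rownames(Dm))]
  alpha <- c(prior$alpha_mean[1], rep(0, ps - 1))
  if (!is.null(prep$lrv_init)) {
    ok <- is.finite(prep$lrv_init)
    if (sum(ok) > 2 * ps)
      alpha <- tryCatch(qr.solve(Dm_full[ok, , drop = FALSE], prep$lrv_init[ok]),
                        error = function(e) alpha)
  }
  alpha <- pmin(pmax(alpha, prior$alpha_mean - prior$alpha_sd),
                prior$alpha_mean + prior$alpha_sd)
  alpha <- alpha + rnorm(ps, 0, 0.1)
  gam <- rep(0, po)
  if (n_obs > 0) gam <- tryCatch(qr.solve(Xo[obs, , drop = FALSE], y2[obs]),
                                 error = function(e) rep(0, po))
  gam <- gam + rnorm(po, 0, 0.05 * pmax(abs(gam), 0.02))
  lam <- c(0, 0, 0)
  Sigma <- prior$Sigma_scale / (prior$Sigma_df + 4) * exp(runif(1, -0.3, 0.3))
  sig_eps <- if (levels3) {
    if (df_ss > 0) sqrt(SS / df_ss) * exp(runif(1, -0.2, 0.2)) else stats::sd(prep$y1) / 2
  } else NA_real_
  sig_u3 <- if (n_obs > 1) {
    max(stats::sd(y2[obs] - Xo[obs, , drop = FALSE] %*% gam), 1e-3)
  } else 1
  u <- matrix(rnorm(J * 3, 0, 0.1), J, 3)

  ## adaptive proposal state; the alpha proposal starts at the Fisher
  ## information of the log-variance regression (~ Xs'Xs / 2)
  log_sc_u2 <- log(0.5)
  log_sc_a <- log(2.38 / sqrt(ps)); log_sc_ar <- log(2.38 / sqrt(ps))
  log_sc_se <- log(0.05); log_sc_s3 <- log(0.1)
  log_sc_t <- log(c(0.2, 0.05, 0.1))   # translation moves
  alpha_hist <- matrix(0, 0, ps)
  prop_chol_a <- tryCatch(chol(2 * chol2inv(chol(crossprod(Xs) + diag(1e-8, ps)))),
                          error = function(e) diag(0.1, ps))
  acc_count <- c(u2 = 0, alpha = 0, alpha_ridge = 0, sig_eps = 0, sig_u3 = 0,
                 t1 = 0, t2 = 0, t3 = 0)
  n_prop <- acc_count

  ## translation-move applicability
  has_t2 <- all(c("s1", "s2") %in% colnames(Xm))
  i_s1 <- match("s1", colnames(Xm)); i_s2 <- match("s2", colnames(Xm))

  fix_lv <- drop(Xs %*% alpha)
  lv <- function() pmin(pmax(fix_lv + u[ji, 3], -LOGVAR_CLIP), LOGVAR_CLIP)
  var_v <- function(s2e) if (levels3) s2e + sig_eps^2 / W else s2e

  n_iter <- config$warmup_draws + config$sampling_draws
  keep <- seq(config$warmup_draws + 1, n_iter, by = config$thin)
  par_names <- prep$par_names
  draws <- matrix(NA_real_, length(keep), length(par_names),
                  dimnames = list(NULL, par_names))
  u_sum <- matrix(0, J, 3); u_sq <- matrix(0, J, 3); n_kept <- 0
  k_row <- 1

  half_norm_lp <- function(s, scale) dnorm(s, 0, scale, log = TRUE)

  for (it in seq_len(n_iter)) {
    warm <- it <= config$warmup_draws
    ## outcome-feedback annealing: the outcome likelihood enters the latent
    ## conditionals with weight rising smoothly from 0 to 1 over the first
    ## half of warmup, so the longitudinal submodel burns in before the
    ## outcome can recruit the weakly identified latent effects; the target
    ## is the exact posterior for every retained draw
    w_y2 <- if (warm) min(1, (it / (0.5 * config$warmup_draws))^2) else 1
    s2e <- exp(lv()); vv <- var_v(s2e)

    ## ---- (u0, u1) exact draw ---------------------------------------------
    S11 <- Sigma[1:2, 1:2]; S12 <- Sigma[1:2, 3]; S22 <- Sigma[3, 3]
    C01 <- S11 - tcrossprod(S12) / S22
    Q <- solve(C01)
    m01 <- outer(u[, 3] / S22, S12)               # J x 2 conditional prior mean
    rfix <- ybar - drop(Xm %*% beta)
    iv <- 1 / vv
    A11 <- rowsum_vec(iv, ji, J); A1z <- rowsum_vec(z * iv, ji, J)
    Azz <- rowsum_vec(z^2 * iv, ji, J)
    b1 <- rowsum_vec(rfix * iv, ji, J); bz <- rowsum_vec(rfix * z * iv, ji, J)
    if (n_obs > 0 && (act[1] || act[2])) {
      r2 <- ifelse(obs, y2 - drop(Xo %*% gam) - lam[3] * u[, 3], 0)
      w3 <- w_y2 * as.numeric(obs) / sig_u3^2
      A11 <- A11 + lam[1]^2 * w3; A1z <- A1z + lam[1] * lam[2] * w3
      Azz <- Azz + lam[2]^2 * w3
      b1 <- b1 + lam[1] * r2 * w3; bz <- bz + lam[2] * r2 * w3
    }
    P11 <- Q[1, 1] + A11; P12 <- Q[1, 2] + A1z; P22 <- Q[2, 2] + Azz
    rhs1 <- Q[1, 1] * m01[, 1] + Q[1, 2] * m01[, 2] + b1
    rhs2 <- Q[2, 1] * m01[, 1] + Q[2, 2] * m01[, 2] + bz
    detP <- P11 * P22 - P12^2
    c11 <- P22 / detP; c12 <- -P12 / detP; c22 <- P11 / detP
    mu0 <- c11 * rhs1 + c12 * rhs2
    mu1 <- c12 * rhs1 + c22 * rhs2
    L11 <- sqrt(c11); L21 <- c12 / L11; L22 <- sqrt(pmax(c22 - L21^2, 1e-300))
    e1 <- rnorm(J); e2 <- rnorm(J)
    u[, 1] <- mu0 + L11 * e1
    u[, 2] <- mu1 + L21 * e1 + L22 * e2

    ## ---- u2 vectorized Metropolis ----------------------------------------
    kc <- drop(solve(S11 + diag(1e-12, 2), S12)) # regression of u2 on (u0,u1)
    m2 <- drop(u[, 1:2] %*% kc)
    c2 <- max(S22 - sum(S12 * kc), 1e-12)
    rmean <- ybar - drop(Xm %*% beta) - u[ji, 1] - u[ji, 2] * z
    for (rf in seq_len(config$u2_refresh)) {
      u2c <- u[, 3]
      u2p <- u2c + exp(log_sc_u2) * rnorm(J)
      lvc <- pmin(pmax(fix_lv + u2c[ji], -LOGVAR_CLIP), LOGVAR_CLIP)
      lvp <- pmin(pmax(fix_lv + u2p[ji], -LOGVAR_CLIP), LOGVAR_CLIP)
      vc <- var_v(exp(lvc)); vp <- var_v(exp(lvp))
      llc <- rowsum_vec(-0.5 * (log(vc) + rmean^2 / vc), ji, J)
      llp <- rowsum_vec(-0.5 * (log(vp) + rmean^2 / vp), ji, J)
      if (n_obs > 0 && act[3]) {
        r2b <- y2 - drop(Xo %*% gam) - lam[1] * u[, 1] - lam[2] * u[, 2]
        r2b[!obs] <- 0
        llc <- llc - w_y2 * as.numeric(obs) * 0.5 * (r2b - lam[3] * u2c)^2 / sig_u3^2
        llp <- llp - w_y2 * as.numeric(obs) * 0.5 * (r2b - lam[3] * u2p)^2 / sig_u3^2
      }
      lr <- llp - llc +
        dnorm(u2p, m2, sqrt(c2), log = TRUE) - dnorm(u2c, m2, sqrt(c2), log = TRUE)
      accept <- log(runif(J)) < lr
      u[accept, 3] <- u2p[accept]
      n_prop["u2"] <- n_prop["u2"] + 1
      acc_rate <- mean(accept)
      acc_count["u2"] <- acc_count["u2"] + acc_rate
      if (warm) log_sc_u2 <- adapt_scale(log_sc_u2, acc_rate, 0.44, it)
    }

    ## ---- Sigma_u conjugate inverse-Wishart block draw ----------------------
    Spost <- prior$Sigma_scale + crossprod(u)
    Wdraw <- stats::rWishart(1, prior$Sigma_df + J, solve(Spost))[, , 1]
    Sigma <- chol2inv(chol(Wdraw))
    Sigma <- (Sigma + t(Sigma)) / 2

    ## ---- beta exact draw --------------------------------------------------
    s2e <- exp(lv()); vv <- var_v(s2e); iv <- 1 / vv
    q <- ybar - u[ji, 1] - u[ji, 2] * z
    XtW <- t(Xm * iv)
    P <- XtW %*% Xm + diag(1 / prior$beta_sd^2, pm)
    rhs <- drop(XtW %*% q) + prior$beta_mean / prior$beta_sd^2
    Lp <- chol(P)
    beta <- backsolve(Lp, backsolve(Lp, rhs, transpose = TRUE) + rnorm(pm))

    ## ---- alpha adaptive Metropolis ---------------------------------------
    rmean <- ybar - drop(Xm %*% beta) - u[ji, 1] - u[ji, 2] * z
    a_lp <- function(a) {
      lva <- pmin(pmax(drop(Xs %*% a) + u[ji, 3], -LOGVAR_CLIP), LOGVAR_CLIP)
      va <- var_v(exp(lva))
      -0.5 * sum(log(va) + rmean^2 / va) +
        sum(dnorm(a, prior$alpha_mean, prior$alpha_sd, log = TRUE))
    }
    ap <- alpha + exp(log_sc_a) * drop(rnorm(ps) %*% prop_chol_a)
    lpc <- a_lp(alpha); lpp <- a_lp(ap)
    n_prop["alpha"] <- n_prop["alpha"] + 1
    if (log(runif(1)) < lpp - lpc) {
      alpha <- ap
      fix_lv <- drop(Xs %*% alpha)
      acc_count["alpha"] <- acc_count["alpha"] + 1
      acc <- 1
    } else acc <- 0
    if (warm) {
      log_sc_a <- adapt_scale(log_sc_a, acc, 0.3, it)
      alpha_hist <- rbind(alpha_hist, alpha)
      if (it %% 100 == 0 && nrow(alpha_hist) >= 100) {
        cv <- stats::cov(alpha_hist[max(1, nrow(alpha_hist) - 400):nrow(alpha_hist), ,
                                    drop = FALSE])
        prop_chol_a <- tryCatch(chol(cv + diag(1e-8, ps)), error = function(e) prop_chol_a)
      }
    }

    ## ---- alpha ridge move: shift alpha and compensate u2 by the individual
    ## mean shift, moving along the alpha/u2 ridge ---------------------------
    kc <- drop(solve(Sigma[1:2, 1:2] + diag(1e-12, 2), Sigma[1:2, 3]))
    m2 <- drop(u[, 1:2] %*% kc)
    c2 <- max(Sigma[3, 3] - sum(Sigma[1:2, 3] * kc), 1e-12)
    delta <- exp(log_sc_ar) * drop(rnorm(ps) %*% prop_chol_a)
    ap <- alpha + delta
    shift <- drop(Dm_full %*% delta)            # per-individual u2 compensation
    u2p <- u[, 3] - shift
    lvc <- pmin(pmax(fix_lv + u[ji, 3], -LOGVAR_CLIP), LOGVAR_CLIP)
    lvp <- pmin(pmax(drop(Xs %*% ap) + u2p[ji], -LOGVAR_CLIP), LOGVAR_CLIP)
    vc <- var_v(exp(lvc)); vp <- var_v(exp(lvp))
    lr <- -0.5 * sum(log(vp) + rmean^2 / vp) + 0.5 * sum(log(vc) + rmean^2 / vc) +
      sum(dnorm(ap, prior$alpha_mean, prior$alpha_sd, log = TRUE)) -
      sum(dnorm(alpha, prior$alpha_mean, prior$alpha_sd, log = TRUE)) +
      sum(dnorm(u2p, m2, sqrt(c2), log = TRUE)) -
      sum(dnorm(u[, 3], m2, sqrt(c2), log = TRUE))
    if (n_obs > 0 && lam[3] != 0) {
      r2b <- y2 - drop(Xo %*% gam) - lam[1] * u[, 1] - lam[2] * u[, 2]
      r2b[!obs] <- 0
      lr <- lr - w_y2 * sum(as.numeric(obs) * 0.5 * (r2b - lam[3] * u2p)^2) / sig_u3^2 +
        w_y2 * sum(as.numeric(obs) * 0.5 * (r2b - lam[3] * u[, 3])^2) / sig_u3^2
    }
    n_prop["alpha_ridge"] <- n_prop["alpha_ridge"] + 1
    if (is.finite(lr) && log(runif(1)) < lr) {
      alpha <- ap; u[, 3] <- u2p
      fix_lv <- drop(Xs %*% alpha)
      acc_count["alpha_ridge"] <- acc_count["alpha_ridge"] + 1; acc <- 1
    } else acc <- 0
    if (warm) log_sc_ar <- adapt_scale(log_sc_ar, acc, 0.3, it)

    ## ---- sigma_eps scalar Metropolis on log scale ------------------------
    if (levels3) {
      se_lp <- function(s) {
        va <- exp(lv()) + s^2 / W
        -0.5 * sum(log(va) + rmean^2 / va) +
          (if (df_ss > 0) -df_ss * log(s) - SS / (2 * s^2) else 0) +
          half_norm_lp(s, prior$sigma_eps_scale) + log(s)   # Jacobian of log move
      }
      sp <- sig_eps * exp(exp(log_sc_se) * rnorm(1))
      n_prop["sig_eps"] <- n_prop["sig_eps"] + 1
      if (log(runif(1)) < se_lp(sp) - se_lp(sig_eps)) {
        sig_eps <- sp; acc_count["sig_eps"] <- acc_count["sig_eps"] + 1; acc <- 1
      } else acc <- 0
      if (warm) log_sc_se <- adapt_scale(log_sc_se, acc, 0.44, it)
    }

    ## ---- (gamma, loadings) exact draw ------------------------------------
    if (n_obs > 0) {
      G <- cbind(Xo[obs, , drop = FALSE], u[obs, which(act), drop = FALSE])
      pg <- ncol(G)
      pr_sd <- c(prior$gamma_sd, prior$loading_sd[which(act)])
      pr_mean <- c(prior$gamma_mean, rep(0, sum(act)))
      Pg <- w_y2 * crossprod(G) / sig_u3^2 + diag(1 / pr_sd^2, pg)
      rhsg <- w_y2 * drop(crossprod(G, y2[obs])) / sig_u3^2 + pr_mean / pr_sd^2
      Lg <- chol(Pg)
      gl <- backsolve(Lg, backsolve(Lg, rhsg, transpose = TRUE) + rnorm(pg))
      gam <- gl[seq_len(po)]
      lam <- c(0, 0, 0); lam[which(act)] <- gl[-seq_len(po)]

      ## ---- sigma_u3 scalar Metropolis ------------------------------------
      r3 <- y2[obs] - drop(G %*% gl)
      s3_lp <- function(s) -w_y2 * (n_obs * log(s) + sum(r3^2) / (2 * s^2)) +
        half_norm_lp(s, prior$sigma_u3_scale) + log(s)
      sp <- sig_u3 * exp(exp(log_sc_s3) * rnorm(1))
      n_prop["sig_u3"] <- n_prop["sig_u3"] + 1
      if (log(runif(1)) < s3_lp(sp) - s3_lp(sig_u3)) {
        sig_u3 <- sp; acc_count["sig_u3"] <- acc_count["sig_u3"] + 1; acc <- 1
      } else acc <- 0
      if (warm) log_sc_s3 <- adapt_scale(log_sc_s3, acc, 0.44, it)
    }

    ## ---- translation moves along intercept ridges -------------------------
    Om <- chol2inv(chol(Sigma))
    usum <- colSums(u)
    trans_move <- function(idx, k_u, beta_idx, lam_k, which_t) {
      ## shift fixed effect(s) by delta, u[, k_u] by -delta, gamma0 by lam_k*delta
      delta <- exp(log_sc_t[which_t]) * rnorm(1)
      d_mvn <- delta * sum(Om[k_u, ] * usum) - 0.5 * J * delta^2 * Om[k_u, k_u]
      d_pr <- 0
      if (identical(beta_idx, "alpha0")) {
        d_pr <- d_pr + dnorm(alpha[1] + delta, prior$alpha_mean[1], prior$alpha_sd[1], log = TRUE) -
          dnorm(alpha[1], prior$alpha_mean[1], prior$alpha_sd[1], log = TRUE)
      } else {
        for (bi in beta_idx)
          d_pr <- d_pr + dnorm(beta[bi] + delta, prior$beta_mean[bi], prior$beta_sd[bi], log = TRUE) -
            dnorm(beta[bi], prior$beta_mean[bi], prior$beta_sd[bi], log = TRUE)
      }
      if (n_obs > 0 && lam_k != 0) {
        d_pr <- d_pr + dnorm(gam[1] + lam_k * delta, prior$gamma_mean[1], prior$gamma_sd[1], log = TRUE) -
          dnorm(gam[1], prior$gamma_mean[1], prior$gamma_sd[1], log = TRUE)
      }
      list(delta = delta, lr = d_mvn + d_pr)
    }
    ## (beta0, u0)
    mv <- trans_move(1, 1, 1L, lam[1], 1)
    n_prop["t1"] <- n_prop["t1"] + 1
    if (log(runif(1)) < mv$lr) {
      beta[1] <- beta[1] + mv$delta; u[, 1] <- u[, 1] - mv$delta
      if (n_obs > 0) gam[1] <- gam[1] + lam[1] * mv$delta
      acc_count["t1"] <- acc_count["t1"] + 1; acc <- 1
    } else acc <- 0
    if (warm) log_sc_t[1] <- adapt_scale(log_sc_t[1], acc, 0.44, it)
    ## (spline slopes, u1)
    if (has_t2) {
      mv <- trans_move(1, 2, c(i_s1, i_s2), lam[2], 2)
      n_prop["t2"] <- n_prop["t2"] + 1
      if (log(runif(1)) < mv$lr) {
        beta[i_s1] <- beta[i_s1] + mv$delta; beta[i_s2] <- beta[i_s2] + mv$delta
        u[, 2] <- u[, 2] - mv$delta
        if (n_obs > 0) gam[1] <- gam[1] + lam[2] * mv$delta
        acc_count["t2"] <- acc_count["t2"] + 1; acc <- 1
      } else acc <- 0
      if (warm) log_sc_t[2] <- adapt_scale(log_sc_t[2], acc, 0.44, it)
    }
    ## (alpha0, u2)
    mv <- trans_move(1, 3, "alpha0", lam[3], 3)
    n_prop["t3"] <- n_prop["t3"] + 1
    if (log(runif(1)) < mv$lr) {
      alpha[1] <- alpha[1] + mv$delta; u[, 3] <- u[, 3] - mv$delta
      fix_lv <- drop(Xs %*% alpha)
      if (n_obs > 0) gam[1] <- gam[1] + lam[3] * mv$delta
      acc_count["t3"] <- acc_count["t3"] + 1; acc <- 1
    } else acc <- 0
    if (warm) log_sc_t[3] <- adapt_scale(log_sc_t[3], acc, 0.44, it)

    ## ---- store -------------------------------------------------------------
    if (!warm && ((it - config$warmup_draws) %% config$thin == 0)) {
      sds <- sqrt(diag(Sigma))
      row <- c(beta, alpha, gam, lam[which(act)], sds,
               Sigma[1, 2] / (sds[1] * sds[2]),
               Sigma[1, 3] / (sds[1] * sds[3]),
               Sigma[2, 3] / (sds[2] * sds[3]),
               if (levels3) sig_eps, sig_u3)
      draws[k_row, ] <- row
      k_row <- k_row + 1
      u_sum <- u_sum + u; u_sq <- u_sq + u^2; n_kept <- n_kept + 1
    }
  }
  list(draws = draws, u_sum = u_sum, u_sq = u_sq, n_kept = n_kept,
       accept = acc_count / pmax(n_prop, 1))
}

prepare_fit <- function(design) {
  V <- nrow(design$X_mean)
  vi <- design$meas_visit
  w <- design$w_pooled
  W <- rowsum_vec(w, vi, V)
  ybar <- rowsum_vec(w * design$y1, vi, V) / W
  n_v <- tabulate(vi, nbins = V)
  SS <- sum(w * (design$y1 - ybar[vi])^2)
  df_ss <- sum(n_v - 1)
  spec <- design$spec
  act <- c(location = "location" %in% spec$shared_effects,
           slope = "slope" %in% spec$shared_effects,
           log_scale = "log_scale" %in% spec$shared_effects)
  levels3 <- spec$levels == 3
  par_names <- c(paste0("beta[", colnames(design$X_mean), "]"),
                 paste0("alpha[", colnames(design$X_scale), "]"),
                 paste0("gamma[", colnames(design$X_outcome), "]"),
                 if (any(act)) paste0("gamma[", c("location", "slope", "log_scale")[act], "]"),
                 "sd(u0)", "sd(u1)", "sd(u2)",
                 "cor(u0,u1)", "cor(u0,u2)", "cor(u1,u2)",
                 if (levels3) "sigma_eps", "sigma_u3")
  s1 <- tryCatch(stage_one(design$data, center = design$centers$age),
                 error = function(e) NULL)
  lrv_init <- if (!is.null(s1)) s1$log_resid_var else NULL
  list(V = V, J = nrow(design$X_outcome), Xm = design$X_mean, Xs = design$X_scale,
       Xo = design$X_outcome, z = design$z_age, ji = design$visit_individual,
       ybar = ybar, W = W, SS = SS, df_ss = df_ss, y1 = design$y1,
       y2 = design$y2, obs = !is.na(design$y2), levels3 = levels3, active = act,
       par_names = par_names, lrv_init = lrv_init)
}

#' Fit the joint location-scale model by MCMC
#'
#' Runs the blocked Gibbs/adaptive-Metropolis sampler described in the package
#' vignette and returns pooled posterior draws, a posterior summary
#' (mean, SD, 95% credible interval, split-R-hat, effective sample size), and
#' a convergence report. With the same data, specification, configuration and
#' seed the draws are bitwise reproducible.
#'
#' @param data A `mels_data` object (or a `mels_design` via `design`).
#' @param spec A `mels_spec`.
#' @param config A `mels_fit_config` (see [fit_config()]).
#' @param design Optionally a prebuilt `mels_design` (skips [build_design()]).
#' @return An object of class `mels_fit`.
#' @export
fit_mels <- function(data, spec, config = fit_config(), design = NULL) {
  if (is.null(design)) {
    if (!inherits(data, "mels_data")) stop_jmels("data must be a mels_data object",
                                                 class = "jmels_input_error")
    if (nrow(data$measurements) == 0) stop_jmels("empty dataset", class = "jmels_input_error")
    design <- build_design(data, spec)
  }
  prep <- prepare_fit(design)
  prior <- config$prior_spec %||% default_priors(design)

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1, config$chains)
  chains <- vector("list", config$chains)
  for (c in seq_len(config$chains))
    chains[[c]] <- run_one_chain(prep, config, prior, chain_seeds[c], c)

  draws <- coda::mcmc.list(lapply(chains, function(ch)
    coda::mcmc(ch$draws, start = config$warmup_draws + 1, thin = config$thin)))
  conv <- convergence_diagnostics(draws)
  pooled <- do.call(rbind, lapply(chains, `[[`, "draws"))
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975))
  summ <- data.frame(parameter = colnames(pooled),
                     mean = colMeans(pooled),
                     sd = apply(pooled, 2, stats::sd),
                     q2.5 = qs[1, ], q97.5 = qs[2, ],
                     rhat = conv$table$rhat[match(colnames(pooled), conv$table$parameter)],
                     ess = conv$table$ess[match(colnames(pooled), conv$table$parameter)],
                     row.names = NULL)
  u_sum <- Reduce(`+`, lapply(chains, `[[`, "u_sum"))
  u_sq <- Reduce(`+`, lapply(chains, `[[`, "u_sq"))
  n_kept <- sum(vapply(chains, `[[`, numeric(1), "n_kept"))
  u_mean <- u_sum / n_kept
  u_sd <- sqrt(pmax(u_sq / n_kept - u_mean^2, 0))
  colnames(u_mean) <- colnames(u_sd) <- c("u0", "u1", "u2")

  fit <- structure(list(draws = draws, summary = summ, convergence = conv,
                        accept = lapply(chains, `[[`, "accept"),
                        u_mean = u_mean, u_sd = u_sd,
                        design = design, spec = spec, config = config,
                        prior = prior, seed = config$seed),
                   class = "mels_fit")
  if (!is.na(conv$max_rhat) && conv$max_rhat > 1.05)
    warning("fit did not converge: max split-R-hat = ", round(conv$max_rhat, 3))
  fit
}

#' @export
print.mels_fit <- function(x, digits = 3, ...) {
  cat("Joint location-scale model fit (", length(x$draws), " chains x ",
      nrow(x$draws[[1]]), " draws)\n", sep = "")
  s <- x$summary
  s[, -1] <- lapply(s[, -1], function(col) round(col, digits))
  print(s, row.names = FALSE)
  cat("max split-R-hat:", round(x$convergence$max_rhat, 3),
      "| min ESS:", round(x$convergence$min_ess, 1),
      "|", if (isTRUE(x$convergence$converged)) "converged" else "NOT CONVERGED", "\n")
  invisible(x)
}

## Split-R-hat: each chain is halved; classic between/within variance ratio.
split_rhat <- function(chains_mat) {
  halves <- list()
  for (ch in chains_mat) {
    n <- length(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h)], ch[(n - h + 1):n]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  Wv <- mean(vars)
  Bv <- n * stats::var(means)
  if (!is.finite(Wv) || Wv == 0) return(NA_real_)
  sqrt(((n - 1) / n * Wv + Bv / n) / Wv)
}

convergence_diagnostics <- function(draws) {
  stopifnot(inherits(draws, "mcmc.list"))
  pars <- colnames(draws[[1]])
  rhat <- vapply(pars, function(p)
    split_rhat(lapply(draws, function(ch) as.numeric(ch[, p]))), numeric(1))
  ess <- tryCatch(coda::effectiveSize(draws), error = function(e)
    setNames(rep(NA_real_, length(pars)), pars))
  tab <- data.frame(parameter = pars, rhat = rhat, ess = as.numeric(ess[pars]),
                    row.names = NULL)
  degenerate <- any(!is.finite(rhat))
  list(table = tab,
       max_rhat = suppressWarnings(max(rhat, na.rm = !all(is.na(rhat)))),
       min_ess = suppressWarnings(min(tab$ess, na.rm = !all(is.na(tab$ess)))),
       converged = all(is.finite(rhat)) && max(rhat) <= 1.05,
       degenerate = degenerate)
}

#' Convergence diagnostics for a fit or a set of chains
#'
#' Split-R-hat and effective sample size per sampled quantity, with a
#' pass/fail flag at R-hat <= 1.05. Chains with zero variance make R-hat
#' undefined; these are reported as degenerate with a warning.
#'
#' @param x A `mels_fit` or a `coda::mcmc.list` with >= 2 chains.
#' @return A data frame (parameter, rhat, ess) with attributes `max_rhat`,
#'   `min_ess`, `converged`.
#' @export
convergence_report <- function(x) {
  draws <- if (inherits(x, "mels_fit")) x$draws else x
  if (!inherits(draws, "mcmc.list"))
    stop_jmels("x must be a mels_fit or an mcmc.list", class = "jmels_input_error")
  if (length(draws) < 2)
    stop_jmels("convergence diagnostics need >= 2 chains", class = "jmels_input_error")
  conv <- convergence_diagnostics(draws)
  if (conv$degenerate)
    warning("R-hat undefined for constant (degenerate) chains")
  out <- conv$table
  attr(out, "max_rhat") <- conv$max_rhat
  attr(out, "min_ess") <- conv$min_ess
  attr(out, "converged") <- conv$converged
  out
}

#' Fit a family of shared-random-effect variants
#'
#' Refits the model with different subsets of the random effects entering the
#' outcome model (by default: location only, slope only, log-scale only, and
#' all three) and aligns the loading estimates in one comparison table, on the
#' percentage-change scale used for reporting (per-unit for location and
#' slope, per-10%-increase for the log-scale effect).
#'
#' @param data A `mels_data` object.
#' @param base_spec The full `mels_spec`; variants differ only in
#'   `shared_effects`.
#' @param variants Named list of shared-effect subsets.
#' @param config A `mels_fit_config`.
#' @return A list with `fits` (one `mels_fit` per variant) and `table`
#'   (loading estimates by variant).
#' @export
fit_variants <- function(data, base_spec, variants = list(
                           location = "location", slope = "slope",
                           log_scale = "log_scale",
                           all = c("location", "slope", "log_scale")),
                         config = fit_config()) {
  fits <- list()
  rows <- list()
  for (vn in names(variants)) {
    sp <- base_spec
    sp$shared_effects <- variants[[vn]]
    fits[[vn]] <- fit_mels(data, sp, config)
    pooled <- as.matrix(fits[[vn]]$draws)
    for (eff in c("location", "slope", "log_scale")) {
      pn <- paste0("gamma[", eff, "]")
      if (!pn %in% colnames(pooled)) next
      tr <- if (eff == "log_scale") percent_change_per_10pct(pooled[, pn], name = eff)
            else percent_change_per_unit(pooled[, pn], name = eff)
      rows[[length(rows) + 1]] <- data.frame(variant = vn, effect = eff,
                                             mean = tr$mean, q2.5 = tr$lower,
                                             q97.5 = tr$upper)
    }
  }
  list(fits = fits, table = do.call(rbind, rows))
}
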