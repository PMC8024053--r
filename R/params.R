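#' Parameters of the joint location-scale model
#'
#' Bundles the fixed effects of the three submodels with the variance
#' components: `beta` (exposure mean function), `alpha` (log within-individual
#' variance function), `gamma` (outcome covariate effects), `loadings` (the
#' coefficients of the shared random effects in the outcome model, named by
#' effect), `Sigma_u` (3x3 covariance of the individual location, slope and
#' log-scale effects), `sigma_u3` (outcome residual SD) and `sigma_eps`
#' (within-clinic measurement SD; `NA` for a two-level model). The outcome
#' residual is structurally independent of the other random effects: it never
#' enters `Sigma_u`.
#'
#' @param beta,alpha,gamma Named numeric vectors (names matching the design
#'   columns, `"(Intercept)"` first).
#' @param loadings Named numeric vector with names among
#'   `c("location", "slope", "log_scale")`.
#' @param Sigma_u 3x3 symmetric positive-definite matrix, or `NULL` if
#'   `sd_u`/`cor_u` are given.
#' @param sd_u,cor_u Alternative parameterization: SDs `(u0, u1, u2)` and
#'   correlations `(r01, r02, r12)`.
#' @param sigma_u3 Outcome residual SD (> 0).
#' @param sigma_eps Within-clinic SD (> 0), or `NA` for a two-level model.
#' @return An object of class `mels_params`.
#' @export
mels_params <- function(beta, alpha, gamma, loadings = numeric(0),
                        Sigma_u = NULL, sd_u = NULL, cor_u = NULL,
                        sigma_u3, sigma_eps = NA_real_) {
  if (is.null(Sigma_u)) {
    stopifnot(length(sd_u) == 3, length(cor_u) == 3)
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- cor_u[1]
    R[1, 3] <- R[3, 1] <- cor_u[2]
    R[2, 3] <- R[3, 2] <- cor_u[3]
    Sigma_u <- diag(sd_u) %*% R %*% diag(sd_u)
  }
  Sigma_u <- (Sigma_u + t(Sigma_u)) / 2
  if (!all(dim(Sigma_u) == c(3, 3)))
    stop_jmels("Sigma_u must be 3x3", class = "jmels_contract_error")
  ## Positive semi-definite is accepted (the zero-variance limit is a valid
  ## generator setting); density evaluation requires strict definiteness and
  ## raises its own error.
  ev <- eigen(Sigma_u, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(1, abs(ev[1])))
    stop_jmels("Sigma_u is not positive semi-definite (min eigenvalue ",
               signif(min(ev), 3), ")", class = "jmels_definiteness_error")
  if (!is.finite(sigma_u3) || sigma_u3 < 0)
    stop_jmels("sigma_u3 must be >= 0", class = "jmels_contract_error")
  if (!is.na(sigma_eps) && sigma_eps < 0)
    stop_jmels("sigma_eps must be >= 0", class = "jmels_contract_error")
  bad <- setdiff(names(loadings), c("location", "slope", "log_scale"))
  if (length(bad)) stop_jmels("unknown loading name(s): ", paste(bad, collapse = ", "),
                              class = "jmels_contract_error")
  dimnames(Sigma_u) <- list(c("u0", "u1", "u2"), c("u0", "u1", "u2"))
  structure(list(beta = beta, alpha = alpha, gamma = gamma, loadings = loadings,
                 Sigma_u = Sigma_u, sigma_u3 = sigma_u3, sigma_eps = sigma_eps),
            class = "mels_params")
}

#' @export
print.mels_params <- function(x, ...) {
  cat("Joint location-scale model parameters\n")
  cat("  beta: ", paste(signif(x$beta, 4), collapse = ", "), "\n")
  cat("  alpha:", paste(signif(x$alpha, 4), collapse = ", "), "\n")
  cat("  gamma:", paste(signif(x$gamma, 4), collapse = ", "), "\n")
  if (length(x$loadings))
    cat("  loadings:", paste(names(x$loadings), signif(x$loadings, 4), sep = "=", collapse = ", "), "\n")
  sds <- sqrt(diag(x$Sigma_u))
  cat("  SD(u0, u1, u2) =", paste(signif(sds, 4), collapse = ", "),
      "; correlations =", paste(signif(implied_correlations(x$Sigma_u), 3), collapse = ", "), "\n")
  cat("  sigma_u3 =", signif(x$sigma_u3, 4), "; sigma_eps =", signif(x$sigma_eps, 4), "\n")
  invisible(x)
}

#' Correlations implied by a random-effect covariance matrix
#'
#' @param Sigma_u 3x3 positive-definite covariance matrix of the location,
#'   slope and log-scale random effects.
#' @return Named vector of the three correlations: location-slope,
#'   location-log-scale, slope-log-scale.
#' @examples
#' implied_correlations(diag(3))
#' @export
implied_correlations <- function(Sigma_u) {
  Sigma_u <- (Sigma_u + t(Sigma_u)) / 2
  ev <- eigen(Sigma_u, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_jmels("Sigma_u is not positive definite", class = "jmels_definiteness_error")
  s <- sqrt(diag(Sigma_u))
  c(`cor(u0,u1)` = Sigma_u[1, 2] / (s[1] * s[2]),
    `cor(u0,u2)` = Sigma_u[1, 3] / (s[1] * s[3]),
    `cor(u1,u2)` = Sigma_u[2, 3] / (s[2] * s[3]))
}

#' Serialize parameters to a flat JSON/YAML file
#'
#' `Sigma_u` is stored as SDs plus correlations so the file is human-editable;
#' [read_params()] reassembles and re-validates the matrix.
#'
#' @param params A `mels_params` object.
#' @param path Output path ending in `.json` or `.yaml`/`.yml`.
#' @return Invisibly, `path`.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "mels_params"))
  flat <- list(beta = as.list(params$beta), alpha = as.list(params$alpha),
               gamma = as.list(params$gamma), loadings = as.list(params$loadings),
               sd_u = sqrt(diag(params$Sigma_u)),
               cor_u = unname(implied_correlations(params$Sigma_u)),
               sigma_u3 = params$sigma_u3, sigma_eps = params$sigma_eps)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  flat <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  mels_params(beta = unlist(flat$beta), alpha = unlist(flat$alpha),
              gamma = unlist(flat$gamma), loadings = unlist(flat$loadings) %||% numeric(0),
              sd_u = unlist(flat$sd_u), cor_u = unlist(flat$cor_u),
              sigma_u3 = flat$sigma_u3,
              sigma_eps = flat$sigma_eps %||% NA_real_)
}

#' Individual random effects
#'
#' One `(u0, u1, u2)` triple per individual: deviations of the individual's
#' intercept (location), age slope, and log within-individual variance from
#' the population values.
#'
#' @param u Numeric J x 3 matrix (columns `u0`, `u1`, `u2`).
#' @return An object of class `mels_effects` (a matrix).
#' @export
mels_effects <- function(u) {
  u <- as.matrix(u)
  if (ncol(u) != 3) stop_jmels("random effects must have 3 columns", class = "jmels_contract_error")
  colnames(u) <- c("u0", "u1", "u2")
  class(u) <- c("mels_effects", class(u))
  u
}
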