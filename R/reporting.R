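# Posterior post-processing: the percentage-change transforms used to report
# effects on multiplicatively modeled quantities, residual-based outlier
# screening, and the human-readable results table.

summarize_transformed <- function(draws, name, scale) {
  if (any(!is.finite(draws)))
    stop_jmels("non-finite draws", class = "jmels_contract_error")
  structure(list(name = name, scale = scale, mean = mean(draws),
                 lower = unname(stats::quantile(draws, 0.025)),
                 upper = unname(stats::quantile(draws, 0.975)),
                 draws = draws),
            class = "mels_transformed")
}

#' Percentage change per one-unit increase in a covariate
#'
#' Transforms posterior draws of a log-scale regression coefficient to the
#' percentage change in the modeled quantity per unit increase of the
#' covariate, `(exp(b) - 1) * 100`, applied draw-wise and then summarized
#' (mean and 2.5/97.5 percentiles).
#'
#' @param draws Numeric vector of posterior draws of the coefficient.
#' @param name Optional label.
#' @return A `mels_transformed` object (name, scale, mean, lower, upper,
#'   transformed draws).
#' @examples
#' percent_change_per_unit(log(2))$mean  # 100
#' @export
percent_change_per_unit <- function(draws, name = "") {
  out <- summarize_transformed((exp(draws) - 1) * 100, name, "percent_per_unit")
  out
}

#' Percentage change per 10% increase in a covariate
#'
#' For coefficients of log-transformed covariates: the percentage change in
#' the modeled quantity per 10% increase of the covariate on its natural
#' scale, `(1.10^b - 1) * 100`, applied draw-wise then summarized.
#'
#' @inheritParams percent_change_per_unit
#' @examples
#' percent_change_per_10pct(2)$mean  # 21
#' @export
percent_change_per_10pct <- function(draws, name = "") {
  summarize_transformed((1.10^draws - 1) * 100, name, "percent_per_10pct")
}

#' @export
print.mels_transformed <- function(x, ...) {
  unit <- if (x$scale == "percent_per_unit") "% per unit" else "% per 10% increase"
  cat(x$name, ": ", round(x$mean, 2), unit, " (95% CrI: ", round(x$lower, 2),
      ", ", round(x$upper, 2), ")\n", sep = "")
  invisible(x)
}

#' Residual-based outlier screening
#'
#' Fits a fast homoskedastic three-level growth model (via `lme4`) as the
#' preliminary model, standardizes residuals at the measurement, clinic-visit
#' and individual levels, flags records whose absolute standardized residual
#' exceeds `threshold`, and removes flagged measurements, all measurements of
#' flagged clinic visits, and all rows of flagged individuals. A reproducible
#' proxy for visual quantile-quantile inspection of the residuals.
#'
#' @param data A `mels_data` object.
#' @param spec A `mels_spec` (mean terms feed the preliminary model).
#' @param threshold Positive cutoff on |standardized residual| (default 4).
#' @return A list with `report` (flags per level, residuals, threshold,
#'   counts) and `data` (the filtered `mels_data`).
#' @export
screen_outliers <- function(data, spec, threshold = 4) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop_jmels("threshold must be > 0", class = "jmels_config_error")
  design <- build_design(data, spec)
  df <- data.frame(y = design$y1,
                   visit = design$visit_keys[design$meas_visit],
                   individual = design$individual_ids[design$visit_individual[design$meas_visit]],
                   z = design$z_age[design$meas_visit])
  Xm <- design$X_mean[design$meas_visit, -1, drop = FALSE]
  df <- cbind(df, as.data.frame(Xm))
  fixed <- if (ncol(Xm)) paste0("`", colnames(Xm), "`", collapse = " + ") else "1"
  form <- if (spec$levels == 3) {
    stats::as.formula(paste("y ~", fixed, "+ (1 + z | individual) + (1 | visit)"))
  } else {
    stats::as.formula(paste("y ~", fixed, "+ (1 + z | individual)"))
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))))
  std <- function(x) x / max(stats::sd(x), 1e-12)
  meas_res <- std(stats::resid(fit))
  re <- lme4::ranef(fit)
  flag_meas <- abs(meas_res) > threshold
  if (spec$levels == 3) {
    visit_res <- std(re$visit[["(Intercept)"]])
    names(visit_res) <- rownames(re$visit)
  } else visit_res <- numeric(0)
  ind_res <- std(re$individual[["(Intercept)"]])
  names(ind_res) <- rownames(re$individual)

  flagged_visits <- names(visit_res)[abs(visit_res) > threshold]
  flagged_inds <- names(ind_res)[abs(ind_res) > threshold]

  m <- design$data$measurements
  mkey <- paste(m$individual_id, m$clinic_id)
  drop_m <- flag_meas | mkey %in% flagged_visits | m$individual_id %in% flagged_inds
  cl <- design$data$clinics
  drop_c <- paste(cl$individual_id, cl$clinic_id) %in% flagged_visits |
    cl$individual_id %in% flagged_inds
  ## visits left without measurements are dropped too
  remaining <- unique(paste(m$individual_id[!drop_m], m$clinic_id[!drop_m]))
  drop_c <- drop_c | !(paste(cl$individual_id, cl$clinic_id) %in% remaining)
  ind <- design$data$individuals
  drop_i <- ind$individual_id %in% flagged_inds |
    !(ind$individual_id %in% unique(m$individual_id[!drop_m]))

  filtered <- mels_data(m[!drop_m, , drop = FALSE], cl[!drop_c, , drop = FALSE],
                        ind[!drop_i, , drop = FALSE])
  report <- list(threshold = threshold,
                 measurement = list(flagged = which(flag_meas),
                                    residuals = meas_res),
                 clinic = list(flagged = flagged_visits, residuals = visit_res),
                 individual = list(flagged = flagged_inds, residuals = ind_res),
                 n_removed = c(measurements = sum(drop_m), clinic_visits = sum(drop_c),
                               individuals = sum(drop_i)))
  class(report) <- "mels_outlier_report"
  list(report = report, data = filtered)
}

#' @export
print.mels_outlier_report <- function(x, ...) {
  cat("Outlier screen at |standardized residual| >", x$threshold, "\n")
  cat("  flagged:", length(x$measurement$flagged), "measurement(s),",
      length(x$clinic$flagged), "clinic visit(s),",
      length(x$individual$flagged), "individual(s)\n")
  cat("  removed:", x$n_removed["measurements"], "measurements,",
      x$n_removed["clinic_visits"], "clinic visits,",
      x$n_removed["individuals"], "individuals\n")
  invisible(x)
}

#' Formatted results table from a fitted model
#'
#' Arranges the posterior summary into the conventional presentation:
#' mean-function fixed effects on the raw exposure scale; random-effect SDs
#' and correlations; scale-function effects as percentage change in the
#' within-individual variance (per 10% increase for log-transformed
#' covariates, per unit otherwise; intercept raw); outcome effects as
#' percentage change in the outcome (same footnote logic, with the log-scale
#' loading on the per-10% scale); residual SDs raw. Transforms are applied
#' draw-wise.
#'
#' @param fit A `mels_fit`.
#' @param file Optional path: writes the table as CSV.
#' @return A data frame with columns section, parameter, scale, mean, q2.5,
#'   q97.5.
#' @export
results_table <- function(fit, file = NULL) {
  stopifnot(inherits(fit, "mels_fit"))
  pooled <- as.matrix(fit$draws)
  summ <- fit$summary
  need <- function(p) {
    if (!p %in% colnames(pooled))
      stop_jmels("results_table: required row '", p, "' missing from the fit",
                 class = "jmels_render_error")
    pooled[, p]
  }
  raw_row <- function(section, label, p) {
    d <- need(p)
    data.frame(section = section, parameter = label, scale = "raw",
               mean = mean(d), q2.5 = unname(stats::quantile(d, 0.025)),
               q97.5 = unname(stats::quantile(d, 0.975)))
  }
  pct_row <- function(section, label, p, per10) {
    d <- need(p)
    tr <- if (per10) percent_change_per_10pct(d, label) else percent_change_per_unit(d, label)
    data.frame(section = section, parameter = label,
               scale = tr$scale, mean = tr$mean, q2.5 = tr$lower, q97.5 = tr$upper)
  }
  rows <- list()
  for (tm in c("(Intercept)", fit$spec$mean_terms))
    rows[[length(rows) + 1]] <- raw_row("mean function", tm, paste0("beta[", tm, "]"))
  for (p in c("sd(u0)", "sd(u1)", "sd(u2)", "cor(u0,u1)", "cor(u0,u2)", "cor(u1,u2)"))
    rows[[length(rows) + 1]] <- raw_row("random effects", p, p)
  rows[[length(rows) + 1]] <- raw_row("scale function", "(Intercept)", "alpha[(Intercept)]")
  for (tm in fit$spec$scale_terms)
    rows[[length(rows) + 1]] <- pct_row("scale function", tm, paste0("alpha[", tm, "]"),
                                        per10 = grepl("^log_", tm))
  if (fit$spec$levels == 3)
    rows[[length(rows) + 1]] <- raw_row("scale function", "residual within-clinic SD",
                                        "sigma_eps")
  rows[[length(rows) + 1]] <- raw_row("outcome function", "(Intercept)", "gamma[(Intercept)]")
  for (tm in fit$spec$outcome_terms)
    rows[[length(rows) + 1]] <- pct_row("outcome function", tm, paste0("gamma[", tm, "]"),
                                        per10 = grepl("^log_", tm))
  for (eff in fit$spec$shared_effects)
    rows[[length(rows) + 1]] <- pct_row("outcome function", eff, paste0("gamma[", eff, "]"),
                                        per10 = eff == "log_scale")
  rows[[length(rows) + 1]] <- raw_row("outcome function", "residual SD", "sigma_u3")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
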