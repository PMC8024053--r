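#' Linear spline basis with a single knot
#'
#' Computes the piecewise-linear age basis used in the mean function of the
#' growth model: `s1 = min(age, knot)` and `s2 = max(age - knot, 0)`, so that
#' `s1 + s2 = age` for every age. The default knot of 12 years reflects the
#' change in the systolic blood pressure growth rate around puberty.
#'
#' @param age Numeric vector of ages in years.
#' @param knot Knot location in years (default 12).
#' @return A two-column matrix with columns `s1` and `s2`.
#' @examples
#' spline_basis(c(7.5, 12, 15.5))
#' @export
spline_basis <- function(age, knot = 12) {
  if (!all(is.finite(age))) stop_jmels("spline_basis: non-finite age", class = "jmels_contract_error")
  if (!is.finite(knot)) stop_jmels("spline_basis: non-finite knot", class = "jmels_contract_error")
  cbind(s1 = pmin(age, knot), s2 = pmax(age - knot, 0))
}

#' Model specification for the joint location-scale model
#'
#' Declares which covariate terms enter the mean function, the log-variance
#' (scale) function, and the distal-outcome function, which individual random
#' effects are shared into the outcome model, the spline knot, and whether the
#' model has two levels (one measurement per clinic visit) or three (multiple
#' measurements per visit with a within-clinic error layer).
#'
#' Term names are resolved against the data as follows: `"s1"`/`"s2"` are the
#' spline basis of clinic age; `"age"` is (centered) clinic age; `"a:b"` is the
#' product of the resolved (centered) columns `a` and `b`; `"log_<name>"` is
#' the natural log of covariate `<name>`; any other name is looked up among
#' the clinic-level covariates and then the individual-level covariates.
#' Intercepts are always included and need not be listed. Continuous columns
#' are grand-mean centered; 0/1 indicator columns are left as coded.
#'
#' @param mean_terms Character vector of terms for the exposure mean function.
#' @param scale_terms Character vector of terms for the log-variance function.
#' @param outcome_terms Character vector of terms for the outcome function.
#' @param knot Spline knot in years.
#' @param shared_effects Subset of `c("location", "slope", "log_scale")`
#'   naming the random effects entering the outcome model (may be empty,
#'   giving a location-scale model with an unlinked outcome).
#' @param levels 2 or 3; a two-level model has no within-clinic error layer.
#' @param log_outcome Should the outcome be log-transformed when the design is
#'   built? Default `TRUE` (the outcome is modeled on the log scale).
#' @return An object of class `mels_spec`.
#' @export
mels_spec <- function(mean_terms = c("s1", "s2", "female", "female:s1", "female:s2"),
                      scale_terms = c("age", "female"),
                      outcome_terms = c("age_outcome", "female"),
                      knot = 12,
                      shared_effects = c("location", "slope", "log_scale"),
                      levels = 3,
                      log_outcome = TRUE) {
  shared_effects <- as.character(shared_effects)
  bad <- setdiff(shared_effects, c("location", "slope", "log_scale"))
  if (length(bad)) stop_jmels("unknown shared effect(s): ", paste(bad, collapse = ", "),
                              class = "jmels_contract_error")
  if (!levels %in% c(2, 3)) stop_jmels("levels must be 2 or 3", class = "jmels_contract_error")
  structure(list(mean_terms = as.character(mean_terms),
                 scale_terms = as.character(scale_terms),
                 outcome_terms = as.character(outcome_terms),
                 knot = knot,
                 shared_effects = shared_effects,
                 levels = levels,
                 log_outcome = isTRUE(log_outcome)),
            class = "mels_spec")
}

#' @export
print.mels_spec <- function(x, ...) {
  cat("Joint location-scale model specification (", x$levels, "-level)\n", sep = "")
  cat("  mean    ~ 1 +", paste(x$mean_terms, collapse = " + "), "\n")
  cat("  log-var ~ 1 +", paste(x$scale_terms, collapse = " + "), "\n")
  cat("  outcome ~ 1 +", paste(c(x$outcome_terms, x$shared_effects), collapse = " + "), "\n")
  cat("  spline knot at", x$knot, "years; shared effects:",
      if (length(x$shared_effects)) paste(x$shared_effects, collapse = ", ") else "none", "\n")
  invisible(x)
}

required_measurement_cols <- c("individual_id", "clinic_id", "occasion", "value")
required_clinic_cols <- c("individual_id", "clinic_id", "age")
required_individual_cols <- c("individual_id")

#' Assemble and validate a linked three-table dataset
#'
#' Links the measurement table (one exposure reading per within-clinic
#' occasion), the clinic-visit table (age and time-varying covariates per
#' individual x clinic), and the individual table (static covariates and the
#' distal outcome). Validates key uniqueness, linkage, and finiteness, and
#' sorts all tables canonically by (individual_id, clinic_id, occasion).
#'
#' @param measurements Data frame with columns `individual_id`, `clinic_id`,
#'   `occasion`, `value`, and optionally `n_pooled` (number of raw readings
#'   pooled into a stored value; defaults to 1).
#' @param clinics Data frame with columns `individual_id`, `clinic_id`, `age`,
#'   plus covariate columns.
#' @param individuals Data frame with column `individual_id`, an optional
#'   `outcome` column, plus covariate columns.
#' @return An object of class `mels_data`: a list of the three canonicalized
#'   tables plus a `validation` element with counts.
#' @export
mels_data <- function(measurements, clinics, individuals) {
  measurements <- as.data.frame(measurements)
  clinics <- as.data.frame(clinics)
  individuals <- as.data.frame(individuals)

  chk_cols <- function(df, need, what) {
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop_jmels(what, " table is missing column(s): ", paste(miss, collapse = ", "),
                 class = "jmels_schema_error")
  }
  chk_cols(measurements, required_measurement_cols, "measurement")
  chk_cols(clinics, required_clinic_cols, "clinic")
  chk_cols(individuals, required_individual_cols, "individual")

  if (is.null(measurements$n_pooled)) measurements$n_pooled <- rep(1L, nrow(measurements))
  if (any(!is.finite(measurements$value)))
    stop_jmels("non-finite exposure value(s) in measurement table", class = "jmels_validation_error")
  if (any(!is.finite(measurements$n_pooled)) || any(measurements$n_pooled < 1))
    stop_jmels("n_pooled must be >= 1", class = "jmels_validation_error")
  if (any(measurements$occasion < 1))
    stop_jmels("occasion index must be >= 1", class = "jmels_validation_error")
  if (any(!is.finite(clinics$age)))
    stop_jmels("non-finite age in clinic table", class = "jmels_validation_error")

  mkey <- paste(measurements$individual_id, measurements$clinic_id, measurements$occasion)
  if (anyDuplicated(mkey))
    stop_jmels("duplicate (individual_id, clinic_id, occasion) key(s): ",
               paste(utils::head(unique(mkey[duplicated(mkey)]), 5), collapse = "; "),
               class = "jmels_validation_error")
  ckey <- paste(clinics$individual_id, clinics$clinic_id)
  if (anyDuplicated(ckey))
    stop_jmels("duplicate (individual_id, clinic_id) key(s) in clinic table: ",
               paste(utils::head(unique(ckey[duplicated(ckey)]), 5), collapse = "; "),
               class = "jmels_validation_error")
  if (anyDuplicated(individuals$individual_id))
    stop_jmels("duplicate individual_id in individual table",
               class = "jmels_validation_error")

  mck <- paste(measurements$individual_id, measurements$clinic_id)
  orphan <- !(mck %in% ckey)
  if (any(orphan))
    stop_jmels("measurement(s) reference unknown clinic visit(s): ",
               paste(utils::head(unique(mck[orphan]), 5), collapse = "; "),
               class = "jmels_linkage_error")
  corph <- !(clinics$individual_id %in% individuals$individual_id)
  if (any(corph))
    stop_jmels("clinic visit(s) reference unknown individual(s): ",
               paste(utils::head(unique(clinics$individual_id[corph]), 5), collapse = "; "),
               class = "jmels_linkage_error")
  if (!is.null(individuals$outcome) &&
      any(!is.na(individuals$outcome) & !is.finite(individuals$outcome)))
    stop_jmels("non-finite outcome value(s)", class = "jmels_validation_error")

  measurements <- measurements[order(measurements$individual_id, measurements$clinic_id,
                                     measurements$occasion), , drop = FALSE]
  clinics <- clinics[order(clinics$individual_id, clinics$clinic_id), , drop = FALSE]
  individuals <- individuals[order(individuals$individual_id), , drop = FALSE]
  rownames(measurements) <- rownames(clinics) <- rownames(individuals) <- NULL

  structure(list(measurements = measurements, clinics = clinics, individuals = individuals,
                 validation = list(n_measurements = nrow(measurements),
                                   n_clinic_visits = nrow(clinics),
                                   n_individuals = nrow(individuals))),
            class = "mels_data")
}

#' @export
print.mels_data <- function(x, ...) {
  v <- x$validation
  cat("Linked longitudinal dataset:", v$n_individuals, "individuals,",
      v$n_clinic_visits, "clinic visits,", v$n_measurements, "measurements\n")
  invisible(x)
}

#' Read a linked dataset from delimited files
#'
#' Reads the three input tables from comma- or tab-separated files (delimiter
#' sniffed from the header line) and validates them with [mels_data()]. An
#' optional YAML/JSON config file maps the semantic roles to column names,
#' e.g. `measurements: {individual_id: id, value: sbp}`; roles not listed are
#' assumed to already use the canonical names.
#'
#' @param measurement_file,clinic_file,individual_file Paths to delimited
#'   text files with header rows.
#' @param config Optional path to a YAML or JSON file with per-table
#'   `role: column` maps under keys `measurements`, `clinics`, `individuals`.
#' @return A validated `mels_data` object.
#' @export
read_mels_data <- function(measurement_file, clinic_file, individual_file, config = NULL) {
  remap <- list(measurements = NULL, clinics = NULL, individuals = NULL)
  if (!is.null(config)) {
    cfg <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    for (tab in names(remap)) remap[[tab]] <- cfg[[tab]]
  }
  read_one <- function(path, map) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (!is.null(map)) {
      for (role in names(map)) {
        col <- map[[role]]
        if (!col %in% names(df))
          stop_jmels("configured column '", col, "' not found in ", basename(path),
                     class = "jmels_schema_error")
        names(df)[names(df) == col] <- role
      }
    }
    df
  }
  mels_data(read_one(measurement_file, remap$measurements),
            read_one(clinic_file, remap$clinics),
            read_one(individual_file, remap$individuals))
}

#' Write a linked dataset to delimited files
#'
#' Serializes the three canonical tables as CSV files (`measurements.csv`,
#' `clinics.csv`, `individuals.csv`) plus a `validation.json` report in `dir`.
#' Reading the files back with [read_mels_data()] reproduces the dataset.
#'
#' @param data A `mels_data` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_mels_data <- function(data, dir) {
  stopifnot(inherits(data, "mels_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("measurements.csv", "clinics.csv", "individuals.csv"))
  utils::write.csv(data$measurements, paths[1], row.names = FALSE)
  utils::write.csv(data$clinics, paths[2], row.names = FALSE)
  utils::write.csv(data$individuals, paths[3], row.names = FALSE)
  jsonlite::write_json(data$validation, file.path(dir, "validation.json"), auto_unbox = TRUE)
  invisible(c(paths, file.path(dir, "validation.json")))
}

## Resolve one term name to a raw (untransformed, uncentered) column.
## level: "clinic" (one row per clinic visit) or "individual".
resolve_term_raw <- function(term, data, level) {
  cl <- data$clinics
  ind <- data$individuals
  if (level == "clinic") {
    ind_row <- match(cl$individual_id, ind$individual_id)
    if (term == "age") return(cl$age)
    if (term %in% c("s1", "s2")) return(NULL) # handled by caller (needs knot)
    if (term %in% names(cl)) return(cl[[term]])
    if (term %in% names(ind)) return(ind[[term]][ind_row])
  } else {
    if (term %in% names(ind)) return(ind[[term]])
  }
  NULL
}

## Build one (possibly transformed + centered) design column. Returns
## list(x, center) where center is NA for indicator columns.
build_column <- function(term, data, level, spec, centers = NULL, splines = NULL) {
  if (grepl(":", term, fixed = TRUE)) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    cols <- lapply(parts, build_column, data = data, level = level, spec = spec,
                   centers = centers, splines = splines)
    x <- Reduce(`*`, lapply(cols, `[[`, "x"))
    return(list(x = x, center = NA_real_))
  }
  logit <- grepl("^log_", term)
  base <- sub("^log_", "", term)
  if (term %in% c("s1", "s2") && level == "clinic") {
    raw <- splines[, term]
  } else {
    raw <- resolve_term_raw(if (logit) base else term, data, level)
    if (is.null(raw))
      stop_jmels("term '", term, "' not found among ", level, "-level covariates",
                 class = "jmels_schema_error")
  }
  if (logit) {
    bad <- !is.na(raw) & raw <= 0
    if (any(bad)) {
      ids <- if (level == "clinic") data$clinics$individual_id[bad] else data$individuals$individual_id[bad]
      stop_jmels("cannot log-transform nonpositive '", base, "' for individual(s): ",
                 paste(utils::head(unique(ids), 5), collapse = ", "),
                 class = "jmels_transform_error")
    }
    raw <- log(raw)
  }
  if (is_indicator(raw[!is.na(raw)])) return(list(x = raw, center = NA_real_))
  ctr <- if (!is.null(centers) && term %in% names(centers)) centers[[term]] else mean(raw, na.rm = TRUE)
  list(x = raw - ctr, center = ctr)
}

#' Build design matrices for a model specification
#'
#' Applies the variable transforms and assembles the aligned design matrices:
#' the spline basis is computed on raw age and each basis column is then
#' grand-mean centered; `log_`-prefixed covariates are log-transformed before
#' centering; all other continuous covariates are grand-mean centered; 0/1
#' indicators are left as coded; interaction columns are products of the
#' resolved (centered) components; the outcome is log-transformed when the
#' specification requests it. The random-slope design column is clinic age
#' centered at its grand mean. Individuals missing any term required by the
#' active specification (or the outcome) are dropped (complete case) and the
#' drop count recorded.
#'
#' @param data A `mels_data` object.
#' @param spec A `mels_spec` object.
#' @param centers Optional named list of centering constants to reuse (e.g.
#'   from a design built on another sample); defaults to grand means of the
#'   analysis sample.
#' @param require_outcome Drop individuals with a missing outcome (default
#'   `TRUE`, the complete-case convention). The generator and the
#'   location-scale-only variant keep them: such individuals contribute to the
#'   longitudinal submodel only.
#' @return An object of class `mels_design` containing `X_mean`, `X_scale`
#'   (rows = clinic visits), `X_outcome` (rows = individuals), `z_age`
#'   (centered age per visit), index maps, the transformed outcome `y2`, the
#'   measurement vector `y1` with pooling weights, centering constants, and
#'   drop counts.
#' @export
build_design <- function(data, spec, centers = NULL, require_outcome = TRUE) {
  stopifnot(inherits(data, "mels_data"), inherits(spec, "mels_spec"))
  rng <- range(data$clinics$age)
  uses_spline <- any(c("s1", "s2") %in% unlist(strsplit(
    c(spec$mean_terms, spec$scale_terms), ":", fixed = TRUE)))
  if (uses_spline && (spec$knot < rng[1] || spec$knot > rng[2]))
    stop_jmels("spline knot ", spec$knot, " outside observed age range [",
               round(rng[1], 2), ", ", round(rng[2], 2), "]", class = "jmels_contract_error")

  ## --- complete-case filtering against the active spec -------------------
  need_raw <- function(terms) {
    out <- character(0)
    for (tm in terms) {
      for (p in strsplit(tm, ":", fixed = TRUE)[[1]]) {
        p <- sub("^log_", "", p)
        if (!p %in% c("s1", "s2", "age")) out <- c(out, p)
      }
    }
    unique(out)
  }
  cl <- data$clinics; ind <- data$individuals
  keep <- rep(TRUE, nrow(ind))
  for (v in need_raw(c(spec$mean_terms, spec$scale_terms))) {
    if (v %in% names(cl)) {
      bad_ids <- unique(cl$individual_id[is.na(cl[[v]])])
      keep <- keep & !(ind$individual_id %in% bad_ids)
    } else if (v %in% names(ind)) {
      keep <- keep & !is.na(ind[[v]])
    }
  }
  for (v in need_raw(spec$outcome_terms)) {
    if (!v %in% names(ind))
      stop_jmels("outcome term '", v, "' must be an individual-level covariate",
                 class = "jmels_schema_error")
    keep <- keep & !is.na(ind[[v]])
  }
  if (require_outcome && !is.null(ind$outcome)) keep <- keep & !is.na(ind$outcome)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    kept_ids <- ind$individual_id[keep]
    message("build_design: dropped ", n_dropped,
            " individual(s) with incomplete covariates/outcome (complete case)")
    data <- mels_data(data$measurements[data$measurements$individual_id %in% kept_ids, ],
                      data$clinics[data$clinics$individual_id %in% kept_ids, ],
                      data$individuals[keep, ])
    cl <- data$clinics; ind <- data$individuals
  }
  if (nrow(ind) == 0) stop_jmels("no individuals left after complete-case filtering",
                                 class = "jmels_input_error")

  if (spec$levels == 2) {
    nper <- table(paste(data$measurements$individual_id, data$measurements$clinic_id))
    if (any(nper > 1))
      stop_jmels("a two-level model requires one measurement per clinic visit",
                 class = "jmels_contract_error")
  }

  splines <- spline_basis(cl$age, spec$knot)
  assemble <- function(terms, level) {
    cols <- lapply(terms, build_column, data = data, level = level, spec = spec,
                   centers = centers, splines = splines)
    n <- if (level == "clinic") nrow(cl) else nrow(ind)
    X <- cbind(`(Intercept)` = rep(1, n))
    ctrs <- list()
    for (k in seq_along(terms)) {
      X <- cbind(X, cols[[k]]$x)
      if (!is.na(cols[[k]]$center)) ctrs[[terms[k]]] <- cols[[k]]$center
    }
    colnames(X) <- c("(Intercept)", terms)
    list(X = X, centers = ctrs)
  }
  m <- assemble(spec$mean_terms, "clinic")
  s <- assemble(spec$scale_terms, "clinic")
  o <- assemble(spec$outcome_terms, "individual")

  age_center <- if (!is.null(centers) && "age" %in% names(centers)) centers$age else mean(cl$age)
  z_age <- cl$age - age_center

  y2 <- if (is.null(ind$outcome)) rep(NA_real_, nrow(ind)) else ind$outcome
  if (spec$log_outcome && any(!is.na(y2))) {
    bad <- !is.na(y2) & y2 <= 0
    if (any(bad))
      stop_jmels("cannot log-transform nonpositive outcome for individual(s): ",
                 paste(utils::head(ind$individual_id[bad], 5), collapse = ", "),
                 class = "jmels_transform_error")
    y2 <- log(y2)
  }

  visit_key <- paste(cl$individual_id, cl$clinic_id)
  meas_visit <- match(paste(data$measurements$individual_id, data$measurements$clinic_id),
                      visit_key)
  visit_individual <- match(cl$individual_id, ind$individual_id)

  all_centers <- c(m$centers, s$centers[setdiff(names(s$centers), names(m$centers))],
                   o$centers[setdiff(names(o$centers), c(names(m$centers), names(s$centers)))])
  all_centers$age <- age_center

  structure(list(X_mean = m$X, X_scale = s$X, X_outcome = o$X,
                 z_age = z_age,
                 y1 = data$measurements$value,
                 w_pooled = as.numeric(data$measurements$n_pooled),
                 y2 = y2,
                 meas_visit = meas_visit,
                 visit_individual = visit_individual,
                 individual_ids = ind$individual_id,
                 visit_keys = visit_key,
                 clinic_ids = cl$clinic_id,
                 age = cl$age,
                 centers = all_centers,
                 n_dropped = n_dropped,
                 spec = spec,
                 data = data),
            class = "mels_design")
}

#' @export
print.mels_design <- function(x, ...) {
  cat("Design matrices: ", length(x$y1), " measurements, ", nrow(x$X_mean),
      " clinic visits, ", nrow(x$X_outcome), " individuals\n", sep = "")
  cat("  mean columns:   ", paste(colnames(x$X_mean), collapse = ", "), "\n")
  cat("  scale columns:  ", paste(colnames(x$X_scale), collapse = ", "), "\n")
  cat("  outcome columns:", paste(colnames(x$X_outcome), collapse = ", "), "\n")
  if (x$n_dropped > 0) cat("  dropped (complete case):", x$n_dropped, "individual(s)\n")
  invisible(x)
}
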