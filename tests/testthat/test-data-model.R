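test_that("spline basis matches its definition and sums to age", {
  expect_equal(unname(spline_basis(12, 12)), matrix(c(12, 0), 1))
  expect_equal(unname(spline_basis(7.5, 12)), matrix(c(7.5, 0), 1))
  expect_equal(unname(spline_basis(15.5, 12)), matrix(c(12, 3.5), 1))
  set.seed(1)
  age <- runif(200, 0, 30)
  s <- spline_basis(age, 12)
  expect_equal(s[, "s1"] + s[, "s2"], age)
  expect_error(spline_basis(NA_real_), class = "jmels_contract_error")
})

test_that("dataset assembly validates keys, linkage and finiteness", {
  tt <- tiny_tables()
  d <- mels_data(tt$measurements, tt$clinics, tt$individuals)
  expect_equal(d$validation$n_measurements, 8)
  expect_equal(d$validation$n_clinic_visits, 4)
  expect_equal(d$validation$n_individuals, 2)

  bad <- tt$measurements
  bad$clinic_id[1] <- 99
  expect_error(mels_data(bad, tt$clinics, tt$individuals),
               class = "jmels_linkage_error")

  dup <- rbind(tt$measurements, tt$measurements[1, ])
  expect_error(mels_data(dup, tt$clinics, tt$individuals),
               class = "jmels_validation_error")

  expect_error(mels_data(tt$measurements[, -4], tt$clinics, tt$individuals),
               class = "jmels_schema_error")

  nf <- tt$measurements; nf$value[2] <- Inf
  expect_error(mels_data(nf, tt$clinics, tt$individuals),
               class = "jmels_validation_error")
})

test_that("datasets round-trip through delimited files", {
  tt <- tiny_tables()
  d <- mels_data(tt$measurements, tt$clinics, tt$individuals)
  dir <- tempfile("mels")
  write_mels_data(d, dir)
  d2 <- read_mels_data(file.path(dir, "measurements.csv"),
                       file.path(dir, "clinics.csv"),
                       file.path(dir, "individuals.csv"))
  expect_equal(d2$measurements, d$measurements)
  expect_equal(d2$clinics, d$clinics)
  expect_equal(d2$individuals, d$individuals)
  unlink(dir, recursive = TRUE)
})

test_that("column-role config maps arbitrary column names", {
  tt <- tiny_tables()
  m <- tt$measurements
  names(m)[names(m) == "value"] <- "sbp"
  dir <- tempfile("mels")
  dir.create(dir)
  write.csv(m, file.path(dir, "m.csv"), row.names = FALSE)
  write.csv(tt$clinics, file.path(dir, "c.csv"), row.names = FALSE)
  write.csv(tt$individuals, file.path(dir, "i.csv"), row.names = FALSE)
  yaml::write_yaml(list(measurements = list(value = "sbp")),
                   file.path(dir, "roles.yaml"))
  d <- read_mels_data(file.path(dir, "m.csv"), file.path(dir, "c.csv"),
                      file.path(dir, "i.csv"),
                      config = file.path(dir, "roles.yaml"))
  expect_equal(d$validation$n_measurements, 8)
  unlink(dir, recursive = TRUE)
})

test_that("design transforms: spline then center, logs, indicators", {
  tt <- tiny_tables()
  tt$clinics$age <- c(10, 14, 10, 14)
  tt$clinics$weight <- c(exp(3), exp(5), exp(3), exp(5))
  d <- mels_data(tt$measurements, tt$clinics, tt$individuals)
  spec <- mels_spec(mean_terms = c("s1", "s2", "female", "log_weight"),
                    scale_terms = "age", outcome_terms = "female")
  des <- build_design(d, spec)
  ## raw s1 at ages {10, 14} with knot 12 is {10, 12}; centered {-1, +1}
  expect_equal(unname(des$X_mean[, "s1"]), c(-1, 1, -1, 1))
  expect_equal(des$centers$s1, 11)
  ## log weights {3, 5} centered to {-1, +1}
  expect_equal(unname(des$X_mean[, "log_weight"]), c(-1, 1, -1, 1))
  ## indicator column left as coded
  expect_equal(unname(des$X_mean[, "female"]), c(1, 1, 0, 0))
  ## centered continuous columns have mean ~ 0
  expect_lt(abs(mean(des$X_mean[, "s2"])), 1e-10)
  ## outcome log-transformed
  expect_equal(des$y2, log(c(28, 31)))

  tt$clinics$weight[1] <- 0
  d0 <- mels_data(tt$measurements, tt$clinics, tt$individuals)
  expect_error(build_design(d0, spec), class = "jmels_transform_error")
})

test_that("complete-case filtering drops individuals per the active spec", {
  tt <- tiny_tables()
  tt$individuals$mat_age <- c(NA, 29)
  d <- mels_data(tt$measurements, tt$clinics, tt$individuals)
  spec_with <- mels_spec(mean_terms = c("s1", "s2", "mat_age"),
                         scale_terms = "age", outcome_terms = "female")
  expect_message(des <- build_design(d, spec_with), "dropped 1 individual")
  expect_equal(des$n_dropped, 1)
  expect_equal(des$individual_ids, "b")
  ## a spec not using mat_age keeps both individuals
  des2 <- build_design(d, tiny_spec())
  expect_equal(des2$n_dropped, 0)
})

test_that("build_design is invariant to input row order", {
  sim <- simulate_mels(mels_generator_config(n_individuals = 40, seed = 3))
  d <- sim$data
  set.seed(9)
  shuffled <- mels_data(d$measurements[sample(nrow(d$measurements)), ],
                        d$clinics[sample(nrow(d$clinics)), ],
                        d$individuals[sample(nrow(d$individuals)), ])
  a <- build_design(d, sim$config$spec)
  b <- build_design(shuffled, sim$config$spec)
  expect_equal(b$X_mean, a$X_mean)
  expect_equal(b$X_scale, a$X_scale)
  expect_equal(b$X_outcome, a$X_outcome)
  expect_equal(b$y1, a$y1)
  expect_equal(b$y2, a$y2)
})

test_that("parameters serialize to JSON and YAML and back", {
  p <- default_true_params()
  for (ext in c("params.json", "params.yaml")) {
    path <- file.path(tempdir(), ext)
    write_params(p, path)
    p2 <- read_params(path)
    expect_equal(p2$beta, p$beta)
    expect_equal(p2$Sigma_u, p$Sigma_u, tolerance = 1e-12)
    expect_equal(p2$sigma_eps, p$sigma_eps)
    unlink(path)
  }
})
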