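test_that("null-effect cohort reproduces the closed-form Weibull survival", {
  spec <- synthetic_spec(10000, baseline = list(shape = 1.3, scale = 8),
                         covariates = list(), n_noise_binary = 0,
                         censoring = list(horizon = 1e6, dropout_rate = 0),
                         seed = 42)
  sim <- generate_cohort(spec)
  expect_true(all(sim$cohort$event == 1))
  km <- km_nelson_aalen(sim$cohort$time, sim$cohort$event)
  grid <- quantile(sim$cohort$time, seq(0.02, 0.98, by = 0.02))
  expect_lt(max(abs(km_eval(km, grid, "surv") -
                      weibull_surv(grid, 1.3, 8))), 0.02)
})

test_that("a known binary log-hazard ratio is recovered by a Cox fit", {
  spec <- signal_noise_spec(10000, beta = 0.7, n_noise = 0, seed = 7)
  sim <- generate_cohort(spec)
  co <- sim$cohort
  fit <- fit_cox(matrix(as.numeric(co$values$signal_1), ncol = 1),
                 co$time, co$event)
  expect_lt(abs(fit$coef[1] - 0.7), 2 * fit$se[1])
})

test_that("realised missing fractions hit their targets within 0.01", {
  sim <- generate_cohort(caliber_like_spec(n_patients = 20000, seed = 3))
  mf <- missing_fraction(sim$cohort)
  expect_lt(abs(mf[["heart_rate"]] - 0.92), 0.01)
  expect_lt(abs(mf[["hdl"]] - 0.78), 0.01)
  expect_lt(abs(mf[["total_chol"]] - 0.64), 0.01)
})

test_that("identical spec and seed reproduce the cohort exactly", {
  s1 <- generate_cohort(caliber_like_spec(n_patients = 500, seed = 9))
  s2 <- generate_cohort(caliber_like_spec(n_patients = 500, seed = 9))
  expect_identical(s1, s2)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("event fraction rises as the Weibull scale shrinks", {
  rates <- vapply(c(20, 50, 120), function(sc) {
    spec <- caliber_like_spec(n_patients = 4000, n_noise_binary = 0, seed = 5)
    spec$baseline$scale <- sc
    mean(generate_cohort(spec)$cohort$event)
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("MCAR leaves frailty balanced; MNAR separates it", {
  spec <- caliber_like_spec(n_patients = 20000, n_noise_binary = 0, seed = 11)
  sim <- generate_cohort(spec)
  fr <- sim$truth$frailty
  sep <- function(v) {
    miss <- is.na(sim$cohort$values[[v]])
    se <- sqrt(var(fr[miss]) / sum(miss) + var(fr[!miss]) / sum(!miss))
    (mean(fr[miss]) - mean(fr[!miss])) / se
  }
  expect_lt(abs(sep("wbc")), 3)          # MCAR
  expect_gt(sep("hdl"), 3)               # MNAR, sign +
  expect_lt(sep("creatinine"), -3)       # MNAR, sign -
})

test_that("MNAR decile missingness matches the calibrated logistic model", {
  spec <- caliber_like_spec(n_patients = 20000, n_noise_binary = 0, seed = 13)
  sim <- generate_cohort(spec)
  fr <- sim$truth$frailty
  p <- mnar_probs(fr, rate = 0.5, strength = 1, sign = 1)
  expect_lt(abs(mean(p) - 0.5), 1e-5)
  mask <- with_seed(99, runif(length(fr)) < p)
  dec <- cut(fr, quantile(fr, seq(0, 1, 0.1)), include.lowest = TRUE,
             labels = FALSE)
  top <- mask[dec == 10]; bottom <- mask[dec == 1]
  expect_gt(mean(top), mean(bottom))
  expect_lt(abs(mean(top) - mean(p[dec == 10])), 0.03)
  expect_lt(abs(mean(bottom) - mean(p[dec == 1])), 0.03)
})

test_that("missing-group survival sits on the MNAR sign's side", {
  sim <- generate_cohort(caliber_like_spec(n_patients = 20000,
                                           n_noise_binary = 0, seed = 17))
  co <- sim$cohort
  tmed <- median(co$time)
  for (v in c("hdl", "total_chol")) {   # sign +: missing fares worse
    miss <- is.na(co$values[[v]])
    km_m <- km_nelson_aalen(co$time[miss], co$event[miss])
    km_p <- km_nelson_aalen(co$time[!miss], co$event[!miss])
    expect_lt(km_eval(km_m, tmed, "surv"), km_eval(km_p, tmed, "surv"))
  }
  miss <- is.na(co$values$creatinine)   # sign -: missing fares better
  km_m <- km_nelson_aalen(co$time[miss], co$event[miss])
  km_p <- km_nelson_aalen(co$time[!miss], co$event[!miss])
  expect_gt(km_eval(km_m, tmed, "surv"), km_eval(km_p, tmed, "surv"))
})

test_that("missingness injection handles edge rates and bad input", {
  sim <- generate_cohort(signal_noise_spec(200, n_noise = 2, seed = 1))
  co <- sim$cohort
  out0 <- inject_missingness(co, defs = list(
    missingness_def("signal_1", 0, "MCAR")), seed = 1)
  expect_identical(out0$values$signal_1, co$values$signal_1)
  out1 <- inject_missingness(co, defs = list(
    missingness_def("signal_1", 1, "MCAR")), seed = 1)
  expect_true(all(is.na(out1$values$signal_1)))
  expect_error(missingness_def("signal_1", 1.2, "MCAR"), "rate")
  expect_error(inject_missingness(co, defs = list(
    missingness_def("nope", 0.5, "MCAR")), seed = 1), "unknown variable")
  expect_error(inject_missingness(co, frailty = NULL, defs = list(
    missingness_def("signal_1", 0.5, "MNAR")), seed = 1), "frailty")
})

test_that("spec validation rejects invalid generative models", {
  expect_error(synthetic_spec(0), "positive")
  expect_error(synthetic_spec(10, baseline = list(shape = -1, scale = 5)),
               "shape")
  expect_error(synthetic_spec(10, covariates = list(
    covariate_def("a", "binary", list(type = "bernoulli", p = 0.5)),
    covariate_def("a", "binary", list(type = "bernoulli", p = 0.5)))),
    "unique")
  expect_error(covariate_def("x", "continuous",
                             list(type = "normal", mean = 0, sd = 1),
                             list(type = "linear", beta = Inf)),
               "non-finite")
  expect_error(generate_cohort(synthetic_spec(10, covariates = list(
    covariate_def("x", "continuous", list(type = "weird"))))), "unknown")
})

test_that("cohort CSV + JSON sidecar round-trips", {
  sim <- generate_cohort(caliber_like_spec(n_patients = 120,
                                           n_noise_binary = 3, seed = 21))
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_equal(back$time, sim$cohort$time)
  expect_equal(back$event, sim$cohort$event)
  expect_equal(back$values$smoking, sim$cohort$values$smoking)
  expect_equal(back$values$hdl, sim$cohort$values$hdl)
  expect_equal(vapply(back$meta, `[[`, character(1), "kind"),
               vapply(sim$cohort$meta, `[[`, character(1), "kind"))
})
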