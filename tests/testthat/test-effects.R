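test_that("continuous Cox effects are anchored lines with proportional bands", {
  sim <- generate_cohort(caliber_like_spec(2000, n_noise_binary = 0, seed = 3))
  co <- sim$cohort
  enc <- fit_encoder(co, "indicator")
  fit <- fit_cox(encode(enc, co), co$time, co$event)
  eff <- cox_effect(fit, enc, "age", values = co$values$age)
  # effect and CI are exactly zero at the baseline (z = 0)
  i0 <- which.min(abs(eff$curve$z))
  expect_lt(abs(eff$curve$central[i0]), 0.05)   # grid point nearest zero
  z <- eff$curve$z
  expect_equal(eff$curve$central, fit$coef[["age"]] * z)
  expect_equal(eff$curve$upper - eff$curve$central,
               qnorm(0.975) * fit$se[["age"]] * abs(z))
  # linearity: the effect at 2 SD is twice the effect at 1 SD
  e1 <- fit$coef[["age"]] * 1; e2 <- fit$coef[["age"]] * 2
  expect_equal(e2, 2 * e1)
  # the missing-value point is exposed for encoded variables
  eff_hdl <- cox_effect(fit, enc, "hdl")
  expect_false(is.null(eff_hdl$missing_point))
  expect_error(cox_effect(fit, enc, "nope"), "not in the fit")
})

test_that("discrete bins expose the U shape a linear fit cannot", {
  sim <- generate_cohort(caliber_like_spec(6000, n_noise_binary = 0, seed = 5))
  co <- sim$cohort
  vars <- c("age", "creatinine")
  cosub <- cohort_subset(co, variables = vars)
  encd <- fit_encoder(cosub, "discrete-onehot", n_bins = 10)
  fitd <- fit_cox(encode(encd, cosub), co$time, co$event)
  effd <- cox_effect(fitd, encd, "creatinine")
  bins <- effd$curve[!effd$curve$level %in% "missing", ]
  k <- nrow(bins)
  mid <- bins$central[ceiling(k / 2)]
  expect_gt(bins$central[1], mid - 1e-9)     # first bin above the middle
  expect_gt(bins$central[k], mid)            # last bin above the middle
  # lowest bin is the anchored baseline with zero uncertainty
  expect_equal(bins$central[1], 0)
  expect_equal(bins$upper[1] - bins$lower[1], 0)
  # the continuous fit is a straight line by construction
  encc <- fit_encoder(cosub, "indicator")
  fitc <- fit_cox(encode(encc, cosub), co$time, co$event)
  effc <- cox_effect(fitc, encc, "creatinine", values = co$values$creatinine)
  slope <- diff(effc$curve$central) / diff(effc$curve$z)
  expect_lt(diff(range(slope)), 1e-10)
})

test_that("summed per-variable Cox effects reproduce the linear predictor", {
  sim <- generate_cohort(caliber_like_spec(800, n_noise_binary = 2, seed = 7))
  co <- sim$cohort
  enc <- fit_encoder(co, "indicator")
  dm <- encode(enc, co)
  fit <- fit_cox(dm, co$time, co$event)
  lp <- cox_lp(fit, dm)
  # rebuild each patient's lp from the per-variable effect decomposition
  rebuilt <- rep(0, length(lp))
  for (v in names(co$values)) {
    cols <- fit$descriptors$column[fit$descriptors$variable == v]
    rebuilt <- rebuilt + as.numeric(dm$x[, cols, drop = FALSE] %*%
                                      fit$coef[cols])
  }
  expect_lt(max(abs(rebuilt - lp)), 1e-10)
})

test_that("partial dependence of a linear Cox model recovers the beta-x line", {
  sim <- generate_cohort(caliber_like_spec(2500, n_noise_binary = 0, seed = 9))
  co <- cohort_subset(sim$cohort, variables = c("age", "haemoglobin"))
  enc <- fit_encoder(co, "indicator")
  fit <- fit_cox(encode(enc, co), co$time, co$event)
  bl <- breslow_baseline(fit)
  # a short horizon keeps risks small, where log-risk is linear in lp and
  # the closed-form beta*z line is the exact reference
  risk_fun <- function(x) predict_risk(fit, encode(enc, x), 1.5, baseline = bl)
  pd <- partial_dependence(risk_fun, co, "age", n_patients = 150,
                           grid_size = 25, seed = 2)
  z <- (pd$curve$x - enc$vars$age$center) / enc$vars$age$scale
  beta_line <- fit$coef[["age"]] * z
  # compare shapes after matching each curve's own normalisation
  expect_lt(max(abs((pd$curve$central - mean(pd$curve$central)) -
                      (beta_line - mean(beta_line)))), 0.05 * diff(range(beta_line)))
  # each patient's swept curve averages to zero... on the risk scale the
  # normalisation is by the mean, so exp(curve) has mean 1
  expect_lt(max(abs(rowMeans(exp(pd$patient_curves)) - 1)), 1e-9)
})

test_that("partial dependence of a forest is flat for pure noise", {
  spec <- synthetic_spec(
    2500, baseline = list(shape = 1.1, scale = 10),
    covariates = list(
      covariate_def("driver", "continuous",
                    list(type = "normal", mean = 0, sd = 1),
                    list(type = "linear", beta = 1.0)),
      covariate_def("inert", "continuous",
                    list(type = "normal", mean = 0, sd = 1),
                    list(type = "none"))),
    censoring = list(horizon = 10, dropout_rate = 0.05), seed = 11)
  sim <- generate_cohort(spec)
  # mtry = 2 so the logrank criterion chooses between both variables at
  # every node; mtry = 1 would force half of all splits onto the inert one
  fo <- fit_forest(sim$cohort, forest_params(n_trees = 100, min_node_size = 60,
                                              mtry = 2), seed = 3)
  risk_fun <- function(x) forest_predict(fo, x, 5, seed = 1)
  pd <- partial_dependence(risk_fun, sim$cohort, "inert", n_patients = 120,
                           grid_size = 20, seed = 4)
  expect_lt(max(abs(pd$curve$central)), 0.05)
  # the driving variable's dependence is monotone over the central grid
  pdd <- partial_dependence(risk_fun, sim$cohort, "driver", n_patients = 120,
                            grid_size = 20, seed = 5)
  central <- pdd$curve$central[3:18]
  expect_gt(cor(central, seq_along(central)), 0.9)
})

test_that("missing-vs-present curves require both groups and report the sign", {
  sim <- generate_cohort(caliber_like_spec(6000, n_noise_binary = 0, seed = 13))
  co <- sim$cohort
  mc <- missingness_curves(co, "hdl", horizon = 5)
  expect_true(mc$worse_when_missing)        # MNAR sign +
  expect_gt(mc$logrank, 3.84)
  expect_equal(km_eval(mc$km_present, 0, "surv"), 1)
  expect_equal(km_eval(mc$km_missing, 0, "surv"), 1)
  mc2 <- missingness_curves(co, "creatinine", horizon = 5)
  expect_false(mc2$worse_when_missing)      # MNAR sign -
  expect_error(missingness_curves(co, "age", 5), "comparison undefined")
})
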