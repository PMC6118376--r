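test_that("Newton maximiser matches the exact partial-likelihood grid search", {
  t8 <- as.numeric(1:8); e8 <- rep(1L, 8)
  g8 <- c(1, 1, 0, 1, 0, 0, 1, 0)
  b_grid <- grid_search_cox1(g8, t8, e8)
  fit <- fit_cox(matrix(g8, ncol = 1), t8, e8)
  expect_lt(abs(fit$coef[1] - b_grid), 1e-4)
  expect_true(fit$convergence$converged)
})

test_that("degenerate designs error rather than being silently dropped", {
  t8 <- as.numeric(1:8); e8 <- rep(1L, 8)
  x <- cbind(a = rnorm(8), zero = rep(0, 8))
  expect_error(fit_cox(x, t8, e8), "zero")
  x2 <- cbind(a = 1:8, b = 2 * (1:8))
  expect_error(fit_cox(x2, t8, e8), "collinear")
  expect_error(fit_cox(matrix(rnorm(8)), t8, rep(0L, 8)), "no events")
  expect_error(fit_cox(matrix(c(NA, rnorm(7))), t8, e8), "non-finite")
})

test_that("coefficients and errors match an established survival library", {
  skip_if_not_installed("survival")
  for (s in 1:20) {
    d <- withr::with_seed(100 + s, {
      n <- 60 + 5 * s
      x <- matrix(rnorm(n * 3), n, 3)
      tt <- round(rexp(n, exp(x %*% c(0.4, -0.2, 0))), 1) + 0.1
      ev <- rbinom(n, 1, 0.75)
      if (sum(ev) < 3) ev[1:3] <- 1L
      list(x = x, tt = tt, ev = ev)
    })
    for (ties in c("efron", "breslow")) {
      ours <- fit_cox(d$x, d$tt, d$ev, ties = ties)
      ref <- survival::coxph(survival::Surv(d$tt, d$ev) ~ d$x, ties = ties)
      expect_lt(max(abs(ours$coef - unname(coef(ref)))), 1e-4)
      expect_lt(max(abs(ours$se - unname(sqrt(diag(vcov(ref)))))), 1e-4)
    }
  }
})

test_that("Efron and Breslow agree exactly on tie-free data", {
  d <- withr::with_seed(77, {
    n <- 200
    x <- matrix(rnorm(n * 2), n, 2)
    list(x = x, tt = rexp(n, exp(x[, 1] * 0.5)), ev = rbinom(n, 1, 0.8))
  })
  fe <- fit_cox(d$x, d$tt, d$ev, ties = "efron")
  fb <- fit_cox(d$x, d$tt, d$ev, ties = "breslow")
  expect_lt(max(abs(fe$coef - fb$coef)), 1e-8)
})

test_that("the fit is invariant to affine rescaling of a column", {
  d <- withr::with_seed(78, {
    n <- 300
    x <- cbind(a = rnorm(n, 5, 2), b = rbinom(n, 1, 0.4))
    list(x = x, tt = rexp(n, exp(0.3 * scale(x[, 1]))), ev = rbinom(n, 1, 0.7))
  })
  f1 <- fit_cox(d$x, d$tt, d$ev)
  x2 <- d$x; x2[, 1] <- x2[, 1] * 10
  f2 <- fit_cox(x2, d$tt, d$ev)
  expect_lt(abs(f1$coef[1] - 10 * f2$coef[1]) * sd(d$x[, 1]), 1e-6)
  expect_lt(abs(f1$coef[2] - f2$coef[2]), 1e-6)
})

test_that("the null-model Breslow baseline is the Nelson-Aalen estimator", {
  d <- withr::with_seed(79, {
    n <- 150
    list(x = matrix(rbinom(n, 1, 0.5), ncol = 1),
         tt = round(rexp(n, 0.3), 1) + 0.05, ev = rbinom(n, 1, 0.7))
  })
  fit <- fit_cox(d$x, d$tt, d$ev)
  fit$coef[] <- 0                       # force the null model
  bl <- breslow_baseline(fit)
  na <- km_nelson_aalen(d$tt, d$ev)
  expect_equal(bl$time, na$time)
  expect_equal(bl$cumhaz, na$cumhaz, tolerance = 1e-12)
})

test_that("doubling every exp(lp) halves every baseline increment", {
  d <- withr::with_seed(80, {
    n <- 120
    x <- matrix(rnorm(n), ncol = 1)
    list(x = x, tt = rexp(n, exp(0.5 * x[, 1])), ev = rep(1L, n))
  })
  fit <- fit_cox(d$x, d$tt, d$ev)
  bl1 <- breslow_baseline(fit)
  shift <- log(2) / fit$coef[1]
  bl2 <- breslow_baseline(fit, x = d$x + shift, time = d$tt, event = d$ev)
  inc1 <- diff(c(0, bl1$cumhaz))
  inc2 <- diff(c(0, bl2$cumhaz))
  expect_equal(inc2, inc1 / 2, tolerance = 1e-10)
})

test_that("predicted risks are absolute risks: baseline, bounds, KM check", {
  sim <- generate_cohort(signal_noise_spec(4000, beta = 1.2, n_noise = 0,
                                           seed = 14))
  co <- sim$cohort
  x <- matrix(as.numeric(co$values$signal_1), ncol = 1,
              dimnames = list(NULL, "signal_1"))
  fit <- fit_cox(x, co$time, co$event)
  r <- predict_risk(fit, x, horizon = 5)
  expect_true(all(r >= 0 & r <= 1))
  # baseline patient: risk = 1 - exp(-Lambda0)
  bl <- breslow_baseline(fit)
  r0 <- predict_risk(fit, matrix(0, 1, 1), horizon = 5)
  l0 <- max(bl$cumhaz[bl$time <= 5])
  expect_equal(r0, 1 - exp(-l0), tolerance = 1e-12)
  # group risks match group Kaplan-Meier at the horizon within 0.02
  for (g in 0:1) {
    rows <- as.numeric(co$values$signal_1) == g
    km <- km_nelson_aalen(co$time[rows], co$event[rows])
    expect_lt(abs(mean(r[rows]) - (1 - km_eval(km, 5, "surv"))), 0.02)
  }
  expect_warning(predict_risk(fit, x, horizon = 99), "clamp")
})

test_that("the score test at beta = 0 is the logrank statistic", {
  d <- withr::with_seed(81, {
    n <- 250
    g <- rbinom(n, 1, 0.5)
    list(g = g, tt = rexp(n, exp(0.4 * g)), ev = rbinom(n, 1, 0.8))
  })
  dd <- survmiss:::.cox_deriv_cpp(
    matrix(d$g[order(d$tt, decreasing = TRUE)], ncol = 1),
    rep(0, length(d$g)), as.integer(d$ev[order(d$tt, decreasing = TRUE)]),
    sort(d$tt, decreasing = TRUE), TRUE, TRUE)
  score_stat <- dd$grad[1]^2 / (-dd$hess[1, 1])
  expect_lt(abs(score_stat - logrank_statistic(d$tt, d$ev, d$g)), 1e-6)
})

test_that("cox fits serialise to JSON with baseline and convergence record", {
  d <- withr::with_seed(82, {
    n <- 80
    x <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x1"))
    list(x = x, tt = rexp(n, exp(0.3 * x[, 1])), ev = rbinom(n, 1, 0.8))
  })
  fit <- fit_cox(d$x, d$tt, d$ev)
  path <- file.path(tempdir(), "fit.json")
  write_cox_fit(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$coef$x1, unname(fit$coef[1]), tolerance = 1e-12)
  expect_equal(back$ties, "efron")
  expect_true(back$convergence$converged)
  expect_true(all(diff(back$baseline$cumhaz) >= 0))
})
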