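test_that("c-index handles the canonical boundary cases", {
  # risks strictly decreasing in event time, all events: perfect
  tt <- c(1, 2, 3, 4, 5); ev <- rep(1L, 5); r <- c(9, 7, 5, 3, 1)
  expect_equal(c_index(r, tt, ev), 1)
  # all risks equal: pure chance
  expect_equal(c_index(rep(0.5, 5), tt, ev), 0.5)
  # worked 3-patient example: 3 comparable pairs, all concordant
  t3 <- c(2, 4, 5); e3 <- c(1L, 1L, 0L); r3 <- c(0.9, 0.5, 0.1)
  expect_equal(c_index(r3, t3, e3), 1)
  expect_equal(c_index(r3, t3, e3), brute_cindex(r3, t3, e3))
  expect_error(c_index(1, 5, 0L), "comparable")
})

test_that("fast c-index equals pair enumeration on random censored data", {
  for (s in 1:30) {
    d <- random_surv_data(n = 30 + 6 * s, seed = 600 + s)
    expect_identical(c_index(d$risk, d$time, d$event),
                     brute_cindex(d$risk, d$time, d$event))
  }
})

test_that("c-index is rank-based: monotone transforms and reversal", {
  d <- random_surv_data(200, tie_prob = 0, seed = 640)
  r <- rnorm(200)
  c1 <- c_index(r, d$time, d$event)
  expect_equal(c_index(exp(3 * r), d$time, d$event), c1)
  expect_equal(c_index(r, d$time, d$event) + c_index(-r, d$time, d$event), 1)
})

test_that("true risks are nearly perfectly calibrated; mis-scaling hurts", {
  sim <- generate_cohort(signal_noise_spec(10000, beta = 1.3, n_noise = 0,
                                           seed = 15))
  co <- sim$cohort
  g <- as.numeric(co$values$signal_1)
  true_risk <- vapply(c(0, 1), function(gg) {
    km <- km_nelson_aalen(co$time[g == gg], co$event[g == gg])
    1 - km_eval(km, 5, "surv")
  }, numeric(1))[g + 1]
  cal <- calibration_score(true_risk, co$time, co$event, horizon = 5)
  expect_gte(cal$score, 0.97)
  cal_bad <- calibration_score(true_risk^2, co$time, co$event, horizon = 5)
  expect_gte(cal$score, cal_bad$score)
})

test_that("constant predictions give the closed-form calibration area", {
  d <- withr::with_seed(66, {
    n <- 2000
    tt <- rexp(n, 0.1)
    list(tt = tt, ev = rep(1L, n))
  })
  p_true <- mean(d$tt <= 5)
  cal <- calibration_score(rep(0.5, 2000), d$tt, d$ev, horizon = 5)
  # degenerate risk range: area is |observed rate - predicted|
  expect_lt(abs(cal$area - abs(p_true - 0.5)), 0.01)
  # the reported score is clipped to [0.5, 1] with the raw value retained
  low <- calibration_score(rep(0.99, 2000), d$tt, d$ev, horizon = 5)
  expect_gte(low$score, 0.5)
  expect_lte(low$score, 1)
  expect_equal(low$score_raw, 1 - low$area)
  expect_error(calibration_score(runif(30), rexp(30), rbinom(30, 1, 0.5), 5),
               "eligible")
})

test_that("bootstrap intervals behave at the edges and pair correctly", {
  d <- random_surv_data(300, seed = 70)
  b1 <- bootstrap_performance(d$risk, d$time, d$event, "c_index", B = 1,
                              seed = 2)
  expect_equal(b1$lower, b1$upper)
  expect_equal(b1$lower, b1$replicates[1])
  pd <- paired_difference(d$risk, d$risk, d$time, d$event, "c_index", B = 50,
                          seed = 3)
  expect_true(all(pd$differences == 0))
  # same seed, same indices: reproducible estimates
  b2 <- bootstrap_performance(d$risk, d$time, d$event, "c_index", B = 40,
                              seed = 5)
  b3 <- bootstrap_performance(d$risk, d$time, d$event, "c_index", B = 40,
                              seed = 5)
  expect_identical(b2$replicates, b3$replicates)
})

test_that("bootstrap percentile intervals cover the test-set c-index", {
  covered <- 0
  for (s in 1:50) {
    d <- withr::with_seed(700 + s, {
      n <- 250
      r <- rnorm(n)
      tt <- rexp(n, exp(0.8 * r))
      list(r = r, tt = tt, ev = rbinom(n, 1, 0.8))
    })
    full_c <- c_index(d$r, d$tt, d$ev)
    bp <- bootstrap_performance(d$r, d$tt, d$ev, "c_index", B = 100, seed = s)
    if (full_c >= bp$lower && full_c <= bp$upper) covered <- covered + 1
  }
  expect_gte(covered / 50, 0.95 - 0.07)
  expect_lte(covered / 50, 1)
})

test_that("KM and Nelson-Aalen are mutually consistent and match survival", {
  skip_if_not_installed("survival")
  sim <- generate_cohort(caliber_like_spec(2000, n_noise_binary = 0,
                                           seed = 19))
  co <- sim$cohort
  km <- km_nelson_aalen(co$time, co$event)
  expect_equal(km_eval(km, 0, "surv"), 1)
  expect_equal(km_eval(km, 0, "cumhaz"), 0)
  grid <- seq(0.5, 9.5, by = 0.5)
  expect_lt(max(abs(km_eval(km, grid, "surv") -
                      exp(-km_eval(km, grid, "cumhaz")))), 0.02)
  sf <- survival::survfit(survival::Surv(co$time, co$event) ~ 1)
  keep <- sf$n.event > 0
  expect_equal(km$surv, sf$surv[keep], tolerance = 1e-12)
})

test_that("the age-only baseline stratifies, pools, and scores by age", {
  sim <- generate_cohort(caliber_like_spec(4000, n_noise_binary = 0,
                                           seed = 23))
  sp <- split_train_test(sim$cohort, 2 / 3, seed = 2)
  ab <- age_baseline(sp$train, sp$test, horizon = 5)
  expect_length(ab$risk, length(sp$test$time))
  expect_true(all(ab$risk >= 0 & ab$risk <= 1))
  # single stratum: every risk is the overall KM risk
  one <- sp$train; one$values$age <- rep(50, length(one$time))
  ote <- sp$test; ote$values$age <- rep(50, length(ote$time))
  ab1 <- age_baseline(one, ote, horizon = 5)
  km <- km_nelson_aalen(one$time, one$event)
  expect_true(all(abs(ab1$risk - (1 - km_eval(km, 5, "surv"))) < 1e-12))
  # risk is informative: c-index above chance
  expect_gt(c_index(ab$risk, sp$test$time, sp$test$event), 0.6)
})
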