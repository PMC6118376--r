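test_that("logrank statistic follows the risk-set tabulation", {
  # identical (time, event) multisets in both groups: perfectly balanced
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4); ev <- rep(1L, 8)
  g <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_equal(logrank_statistic(tt, ev, g), 0)
  # six patients, all events, hand-tabulated O/E/V oracle
  t6 <- as.numeric(1:6); e6 <- rep(1L, 6); g6 <- c(0, 0, 0, 1, 1, 1)
  expect_equal(logrank_statistic(t6, e6, g6), brute_logrank2(t6, e6, g6),
               tolerance = 1e-12)
  expect_error(logrank_statistic(1:4, rep(1L, 4), rep(1, 4)), "two")
})

test_that("logrank agrees with an established implementation, 2 and k groups", {
  skip_if_not_installed("survival")
  for (s in 1:10) {
    d <- withr::with_seed(300 + s, {
      n <- 150
      g <- sample(seq_len(2 + s %% 3), n, replace = TRUE)
      tt <- round(rexp(n, 0.2 * g), 1) + 0.1
      list(g = g, tt = tt, ev = rbinom(n, 1, 0.7))
    })
    ref <- survival::survdiff(survival::Surv(d$tt, d$ev) ~ d$g)$chisq
    expect_equal(logrank_statistic(d$tt, d$ev, d$g), ref, tolerance = 1e-8)
  }
})

test_that("a dominant binary covariate is chosen at the root", {
  d <- withr::with_seed(51, {
    n <- 300
    g <- rbinom(n, 1, 0.5)
    tt <- rexp(n, ifelse(g == 1, 1.5, 0.15))
    list(g = g, tt = tt)
  })
  co <- df_cohort(d$tt, rep(1L, 300),
                  data.frame(g = d$g, junk = withr::with_seed(2, rnorm(300))))
  tree <- grow_tree(co, forest_params(mtry = 2, nsplit = 8,
                                      min_node_size = 100), seed = 3)
  expect_equal(tree$root$type, "split")
  expect_equal(tree$root$var, "g")
  # each leaf hazard equals its group's Nelson-Aalen curve
  left_group <- as.numeric(tree$root$threshold >= 0)  # g <= thr goes left
  for (side in c("left", "right")) {
    leaf <- tree$root[[side]]
    expect_equal(leaf$type, "leaf")
    grp <- if (side == "left") 0 else 1
    km <- km_nelson_aalen(d$tt[d$g == grp], rep(1L, sum(d$g == grp)))
    expect_equal(leaf$haz$cumhaz, km$cumhaz, tolerance = 1e-12)
  }
})

test_that("adaptive imputation routes missing cases by the nonmissing ratio", {
  x <- c(rep(0, 30), rep(1, 70), rep(NA, 10000))
  routed <- withr::with_seed(9, survmiss:::route_members(
    x, list(kind = "continuous", threshold = 0), n_iter = 3))
  expect_equal(routed$ratio, 0.30)
  expect_lt(abs(mean(routed$left[101:10100]) - 0.30), 0.01)
})

test_that("routing is unaffected by imputation iterations when nothing is missing", {
  sim <- generate_cohort(signal_noise_spec(400, n_noise = 4, seed = 5))
  p1 <- forest_params(n_trees = 1, mtry = 3, n_impute_iterations = 1)
  p9 <- forest_params(n_trees = 1, mtry = 3, n_impute_iterations = 9)
  t1 <- grow_tree(sim$cohort, p1, seed = 8)
  t9 <- grow_tree(sim$cohort, p9, seed = 8)
  expect_identical(t1$root, t9$root)
})

test_that("every training row reaches exactly one leaf per tree", {
  sim <- generate_cohort(caliber_like_spec(600, n_noise_binary = 5, seed = 6))
  tree <- grow_tree(sim$cohort, forest_params(min_node_size = 20), seed = 2)
  frame <- survmiss:::forest_frame(sim$cohort)
  pieces <- withr::with_seed(3, survmiss:::tree_leaves_for(
    tree$root, seq_along(sim$cohort$time), frame$cols))
  idx <- unlist(lapply(pieces, `[[`, "idx"))
  expect_equal(sort(idx), seq_along(sim$cohort$time))
  # leaf member counts respect the minimum node size
  sizes <- unlist(lapply(pieces, function(p) p$leaf$n))
  expect_true(all(sizes >= 20))
})

test_that("the ensemble cumulative hazard is non-decreasing for every patient", {
  sim <- generate_cohort(caliber_like_spec(500, n_noise_binary = 3, seed = 7))
  fo <- fit_forest(sim$cohort, forest_params(n_trees = 25), seed = 4)
  chf <- forest_predict(fo, sim$cohort, times = c(1, 2, 4, 6, 8), seed = 1,
                        type = "chf")
  expect_true(all(apply(chf, 1, function(r) all(diff(r) >= 0))))
})

test_that("covariate-free ensembles reproduce the training Kaplan-Meier", {
  sim <- generate_cohort(signal_noise_spec(800, beta = 0, n_noise = 3,
                                           seed = 8))
  co <- sim$cohort
  fo <- fit_forest(co, forest_params(n_trees = 100), seed = 5)
  grid <- seq(0.25, 9.5, by = 0.25)
  surv <- exp(-colMeans(forest_predict(fo, co, grid, seed = 2, type = "chf")))
  km <- km_eval(km_nelson_aalen(co$time, co$event), grid, "surv")
  expect_lt(max(abs(surv - km)), 0.03)
})

test_that("split partitions are invariant to monotone transforms", {
  d <- withr::with_seed(52, {
    n <- 400
    x <- rlnorm(n, 0, 0.6)
    list(x = x, tt = rexp(n, exp(0.8 * log(x))), ev = rbinom(n, 1, 0.8))
  })
  co1 <- df_cohort(d$tt, d$ev, data.frame(v = d$x))
  co2 <- df_cohort(d$tt, d$ev, data.frame(v = log(d$x)))
  pars <- forest_params(n_trees = 1, mtry = 1, nsplit = 5, min_node_size = 40)
  t1 <- grow_tree(co1, pars, seed = 6)
  t2 <- grow_tree(co2, pars, seed = 6)
  assign1 <- withr::with_seed(1, survmiss:::tree_leaves_for(
    t1$root, seq_len(400), survmiss:::forest_frame(co1)$cols))
  assign2 <- withr::with_seed(1, survmiss:::tree_leaves_for(
    t2$root, seq_len(400), survmiss:::forest_frame(co2)$cols))
  expect_equal(lapply(assign1, `[[`, "idx"), lapply(assign2, `[[`, "idx"))
})

test_that("prediction variance shrinks as trees are added", {
  sim <- generate_cohort(caliber_like_spec(500, n_noise_binary = 2, seed = 9))
  co <- sim$cohort
  risk_sd <- function(n_trees) {
    risks <- vapply(1:5, function(s) {
      fo <- fit_forest(co, forest_params(n_trees = n_trees), seed = s)
      mean(forest_predict(fo, co, 5, seed = 1))
    }, numeric(1))
    sd(risks)
  }
  expect_lt(risk_sd(50), risk_sd(1))
})

test_that("forests refuse cohorts lacking training variables", {
  sim <- generate_cohort(signal_noise_spec(300, n_noise = 3, seed = 10))
  fo <- fit_forest(sim$cohort, forest_params(n_trees = 3), seed = 1)
  stripped <- cohort_subset(sim$cohort,
                            variables = names(sim$cohort$values)[-1])
  expect_error(forest_predict(fo, stripped, 5), "lacks variables")
  expect_error(grow_tree(cohort_subset(sim$cohort, integer(0))), "positive|empty")
})
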