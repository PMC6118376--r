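# Independent oracles and small fixture builders used across the suite.

# O(n^2) pair-enumeration concordance oracle (Harrell conventions: the
# shorter time must be an event; time-tied double-event pairs excluded;
# risk ties score 1/2). Enumerates every ordered pair (i, j) with i the
# event member, one row of comparisons at a time.
brute_cindex <- function(risk, time, event) {
  n <- length(time)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    comp <- (time > time[i]) | (time == time[i] & event == 0)
    comp[i] <- FALSE
    den <- den + sum(comp)
    num <- num + sum(comp & risk[i] > risk) +
      0.5 * sum(comp & risk[i] == risk)
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# risk-set tabulation logrank oracle for two groups: explicit O, E, V sums
brute_logrank2 <- function(time, event, group) {
  ut <- sort(unique(time[event == 1]))
  oe <- v <- 0
  for (t in ut) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    if (n > 1) {
      oe <- oe + d1 - d * n1 / n
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  if (v == 0) return(0)
  oe^2 / v
}

# exact 1-d log partial likelihood grid search (no ties assumed)
grid_search_cox1 <- function(x, time, event, grid = seq(-5, 5, by = 1e-4)) {
  pl <- function(b) {
    lp <- b * x
    s <- 0
    for (i in seq_along(time)) {
      if (event[i] == 1)
        s <- s + lp[i] - log(sum(exp(lp[time >= time[i]])))
    }
    s
  }
  vals <- vapply(grid, pl, numeric(1))
  grid[which.max(vals)]
}

weibull_surv <- function(t, shape, scale) exp(-(t / scale)^shape)

# build a cohort directly from vectors (numeric/factor columns)
df_cohort <- function(time, event, values, sources = NULL) {
  values <- as.data.frame(values, optional = TRUE)
  meta <- lapply(names(values), function(v) {
    x <- values[[v]]
    if (is.factor(x)) {
      list(name = v, kind = "categorical", labels = levels(x),
           source = if (is.null(sources)) "expert" else sources[[v]])
    } else if (all(stats::na.omit(x) %in% c(0, 1)) &&
               length(unique(stats::na.omit(x))) <= 2) {
      list(name = v, kind = "binary", labels = c("0", "1"),
           source = if (is.null(sources)) "expert" else sources[[v]])
    } else {
      list(name = v, kind = "continuous", labels = NULL,
           source = if (is.null(sources)) "expert" else sources[[v]])
    }
  })
  names(meta) <- names(values)
  new_cohort(sprintf("P%05d", seq_along(time)), time, event, values, meta)
}

# random censored survival data for oracle-equivalence sweeps
random_surv_data <- function(n, tie_prob = 0.3, seed = 1) {
  withr::with_seed(seed, {
    time <- if (runif(1) < tie_prob) sample(1:10, n, replace = TRUE) + 0 else
      round(rexp(n, 0.2), 2) + 0.01
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[sample.int(n, 1)] <- 1L
    risk <- if (runif(1) < 0.5) rnorm(n) else sample(seq(0, 1, 0.1), n, TRUE)
    list(time = time, event = event, risk = risk)
  })
}

# a small cohort with one strong binary effect and optional noise, used by
# several modules
signal_noise_spec <- function(n, beta = 1.0, n_noise = 50, seed = 1,
                              n_signal = 1) {
  covs <- lapply(seq_len(n_signal), function(i) {
    covariate_def(sprintf("signal_%d", i), "binary",
                  list(type = "bernoulli", p = 0.4),
                  list(type = "linear", beta = beta))
  })
  synthetic_spec(n, baseline = list(shape = 1.1, scale = 12),
                 covariates = covs, n_noise_binary = n_noise,
                 censoring = list(horizon = 10, dropout_rate = 0.05),
                 seed = seed)
}

# one-hot style binary design with 5 strong columns and 200 nulls
enet_fixture_acc <- function(n, seed = 1) {
  withr::with_seed(seed, {
    p <- 205
    x <- matrix(rbinom(n * p, 1, 0.3), n, p)
    b <- c(1, -1, 1, -1, 1, rep(0, 200))
    tt <- rexp(n, 0.08 * exp(x %*% b))
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 20) ev[1:20] <- 1L
    list(x = x, time = tt, event = ev, beta = b)
  })
}

# clean strong-signal fixture: strong continuous + binary effects, no
# missingness
strong_signal_spec <- function(n, seed = 1) {
  covs <- list(
    covariate_def("age", "continuous", list(type = "normal", mean = 65, sd = 10),
                  list(type = "linear", beta = 0.8)),
    covariate_def("marker", "continuous",
                  list(type = "lognormal", meanlog = 0, sdlog = 0.5),
                  list(type = "linear", beta = 0.5)),
    covariate_def("biomarker_u", "continuous",
                  list(type = "lognormal", meanlog = log(90), sdlog = 0.25),
                  list(type = "ushape", a = 0.4, b = 0.1)),
    covariate_def("flag", "binary", list(type = "bernoulli", p = 0.3),
                  list(type = "linear", beta = 0.6))
  )
  synthetic_spec(n, baseline = list(shape = 1.2, scale = 18),
                 covariates = covs, n_noise_binary = 5,
                 censoring = list(horizon = 10, dropout_rate = 0.03),
                 seed = seed)
}
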