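#' Harrell's concordance index
#'
#' The probability that, of two comparable patients, the one who dies first
#' carries the higher predicted risk. A pair is comparable when the shorter
#' follow-up ends in an event (pairs tied on time with two events are not
#' comparable); risk-tied comparable pairs score 1/2. Computed by an
#' O(n log n) rank-tree sweep.
#'
#' @param risk risk scores (higher = predicted to die earlier).
#' @param time,event outcome.
#' @return value in `[0, 1]`; errors when no pair is comparable.
#' @export
c_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  ct <- .cindex_counts_cpp(as.numeric(time), as.integer(event),
                           as.numeric(risk))
  if (ct$comparable == 0) stop_sm("no comparable pairs")
  (ct$concordant + 0.5 * ct$tied_risk) / ct$comparable
}

#' Calibration curve and calibration-area score at a horizon
#'
#' Patients are scored by predicted risk of death by the horizon and their
#' observed binary status at that date (patients censored before the horizon
#' are excluded). A locally smoothed regression of outcome on predicted risk
#' is compared to the ideal line `y = x`; the area `a` between the two over
#' the observed risk range measures miscalibration and the score is `1 - a`,
#' reported clipped to `[0.5, 1]` with the raw value retained.
#'
#' @param risk predicted risks at the horizon, in `[0, 1]`.
#' @param time,event outcome.
#' @param horizon horizon in years (> 0).
#' @param smoother_fraction fraction of points in each local-linear window
#'   (default 0.3).
#' @param min_eligible minimum eligible patients (default 50).
#' @return a `calibration_curve`: `curve` (risk grid, smoothed outcome),
#'   `area`, `score` (`1 - area`, clipped to `[0.5, 1]`), `score_raw`,
#'   `n_eligible`, `range` of observed risks.
#' @export
calibration_score <- function(risk, time, event, horizon,
                              smoother_fraction = 0.3, min_eligible = 50) {
  if (horizon <= 0) stop_sm("horizon must be positive")
  eligible <- (event == 1 & time <= horizon) | time > horizon
  if (sum(eligible) < min_eligible)
    stop_sm("only %d patients are eligible at the horizon (need >= %d)",
            sum(eligible), min_eligible)
  r <- risk[eligible]
  y <- as.numeric(event[eligible] == 1 & time[eligible] <= horizon)
  rng <- range(r)
  if (diff(rng) < 1e-12) {
    # degenerate constant predictions: the curve is the horizontal line at
    # the observed outcome rate and the area is evaluated at that point
    a <- abs(mean(y) - rng[1])
    curve <- data.frame(risk = rng[1], observed = mean(y))
  } else {
    sm <- lowess(r, y, f = smoother_fraction, iter = 0)
    obs <- pmin(pmax(sm$y, 0), 1)
    a <- sum(diff(sm$x) * (abs(obs - sm$x)[-1] + abs(obs - sm$x)[-length(obs)]) / 2)
    curve <- data.frame(risk = sm$x, observed = obs)
  }
  structure(list(curve = curve, area = a, score = min(max(1 - a, 0.5), 1),
                 score_raw = 1 - a, n_eligible = sum(eligible), range = rng),
            class = "calibration_curve")
}

metric_value <- function(metric, risk, time, event, horizon) {
  if (metric == "c_index") c_index(risk, time, event)
  else calibration_score(risk, time, event, horizon)$score
}

#' Bootstrap performance of a model on a held-out test set
#'
#' Resamples test rows with replacement and recomputes the metric on each
#' replicate; reports the point estimate, bootstrap median and 95%
#' percentile interval. Replicates with no comparable pairs (or too few
#' eligible patients) are redrawn and counted.
#'
#' @param risk per-patient risk scores on the test set.
#' @param time,event test outcome.
#' @param metric `"c_index"` or `"calibration"`.
#' @param horizon horizon for the calibration score.
#' @param B bootstrap replicates (default 200).
#' @param seed integer seed.
#' @param indices optional precomputed replicate index matrix (`n x B`), so
#'   several models can share identical replicates.
#' @return a `performance_estimate`: `metric`, `point`, `median`, `lower`,
#'   `upper`, `B`, `seed`, `replicates`.
#' @export
bootstrap_performance <- function(risk, time, event,
                                  metric = c("c_index", "calibration"),
                                  horizon = 5, B = 200, seed = 1,
                                  indices = NULL) {
  metric <- match.arg(metric)
  stopifnot(B >= 1)
  point <- metric_value(metric, risk, time, event, horizon)
  idx <- indices %||% bootstrap_indices(length(time), B, seed)
  reps <- numeric(B)
  redrawn <- 0
  for (b in seq_len(B)) {
    ii <- idx[, b]
    val <- tryCatch(metric_value(metric, risk[ii], time[ii], event[ii],
                                 horizon), error = function(e) NA_real_)
    tries <- 0
    while (is.na(val) && tries < 20) {
      tries <- tries + 1
      redrawn <- redrawn + 1
      ii <- with_seed(child_seed(seed, sprintf("redraw:%d:%d", b, tries)),
                      sample.int(length(time), length(time), replace = TRUE))
      val <- tryCatch(metric_value(metric, risk[ii], time[ii], event[ii],
                                   horizon), error = function(e) NA_real_)
    }
    reps[b] <- val
  }
  if (redrawn > 0) warn_sm("%d degenerate bootstrap replicates redrawn", redrawn)
  qs <- quantile(reps, c(0.025, 0.5, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(metric = metric, point = point, median = qs[2],
                 lower = qs[1], upper = qs[3], B = B, seed = seed,
                 replicates = reps),
            class = "performance_estimate")
}

#' Shared bootstrap replicate indices
#'
#' @param n test-set size.
#' @param B replicates.
#' @param seed integer seed.
#' @return an `n x B` integer matrix.
#' @export
bootstrap_indices <- function(n, B, seed = 1) {
  with_seed(child_seed(seed, "bootstrap_eval"),
            matrix(sample.int(n, n * B, replace = TRUE), n, B))
}

#' Paired bootstrap difference between two models
#'
#' Both models are evaluated on identical replicate indices; the
#' distribution of per-replicate metric differences (A minus B) gives the
#' median difference and a 95% percentile interval.
#'
#' @param risk_a,risk_b risk scores of the two models on the same test rows.
#' @param time,event test outcome.
#' @param metric,horizon,B,seed as in [bootstrap_performance()].
#' @return list: `median`, `lower`, `upper`, `differences`.
#' @export
paired_difference <- function(risk_a, risk_b, time, event,
                              metric = c("c_index", "calibration"),
                              horizon = 5, B = 200, seed = 1) {
  metric <- match.arg(metric)
  stopifnot(length(risk_a) == length(risk_b))
  idx <- bootstrap_indices(length(time), B, seed)
  pa <- bootstrap_performance(risk_a, time, event, metric, horizon, B, seed,
                              indices = idx)
  pb <- bootstrap_performance(risk_b, time, event, metric, horizon, B, seed,
                              indices = idx)
  d <- pa$replicates - pb$replicates
  qs <- quantile(d, c(0.025, 0.5, 0.975), na.rm = TRUE, names = FALSE)
  list(median = qs[2], lower = qs[1], upper = qs[3], differences = d)
}

#' Age-only Kaplan--Meier baseline model
#'
#' The floor model: patients are stratified by integer age in the training
#' set (strata with fewer than `min_stratum` patients pooled with their
#' nearest neighbour), the Kaplan--Meier estimator is computed per stratum,
#' and a test patient's risk is `1 - KM_stratum(horizon)` for their age
#' stratum.
#'
#' @param train,test `cohort`s containing an `age` variable.
#' @param horizon horizon in years.
#' @param age_var name of the age variable (default `"age"`).
#' @param min_stratum minimum training patients per stratum (default 10).
#' @return list: `risk` (test risks), `strata` (breaks), `stratum_risk`.
#' @export
age_baseline <- function(train, test, horizon, age_var = "age",
                         min_stratum = 10) {
  if (!age_var %in% names(train$values)) stop_sm("no '%s' variable", age_var)
  age_tr <- floor(as.numeric(train$values[[age_var]]))
  if (anyNA(age_tr)) stop_sm("ages must be present for the baseline model")
  # pool sparse integer ages into contiguous strata of >= min_stratum
  tab <- table(age_tr)
  ages <- as.integer(names(tab))
  breaks <- numeric(0)
  count <- 0
  for (i in seq_along(ages)) {
    count <- count + tab[i]
    if (count >= min_stratum && i < length(ages)) {
      breaks <- c(breaks, ages[i] + 0.5)
      count <- 0
    }
  }
  if (count < min_stratum && length(breaks) > 0)
    breaks <- breaks[-length(breaks)]
  stratum_of <- function(a) findInterval(a, breaks) + 1L
  s_tr <- stratum_of(age_tr)
  n_strata <- max(s_tr)
  risk_by_stratum <- vapply(seq_len(n_strata), function(s) {
    rows <- s_tr == s
    if (!any(rows)) stop_sm("empty training stratum after pooling")
    km <- km_nelson_aalen(train$time[rows], train$event[rows])
    1 - km_eval(km, horizon, "surv")
  }, numeric(1))
  age_te <- floor(as.numeric(test$values[[age_var]]))
  list(risk = risk_by_stratum[stratum_of(age_te)], strata = breaks,
       stratum_risk = risk_by_stratum)
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf("<performance> %s = %.4f (bootstrap median %.4f, 95%% CI %.4f-%.4f, B=%d)\n",
              x$metric, x$point, x$median, x$lower, x$upper, x$B))
  invisible(x)
}

#' Write a performance report as CSV
#'
#' One row per (model, metric): point, median, 95% bounds, B, seed.
#'
#' @param estimates named list of `performance_estimate`s (names =
#'   `model:metric`).
#' @param path output CSV path.
#' @return the report data frame, invisibly.
#' @export
write_performance_report <- function(estimates, path) {
  rows <- lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(model = sub(":[^:]*$", "", nm), metric = e$metric,
               point = e$point, median = e$median, lower = e$lower,
               upper = e$upper, B = e$B, seed = e$seed)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
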