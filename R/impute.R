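impute_predictor_frame <- function(values, meta, predictors, cumhaz, event) {
  df <- values[, predictors, drop = FALSE]
  for (v in predictors) if (meta[[v]]$kind == "binary")
    df[[v]] <- as.numeric(df[[v]])
  df$.cumhaz <- cumhaz
  df$.event <- event
  df
}

draw_lm <- function(fit, newdata, df_res) {
  # posterior-style draw: sigma^2 from scaled inverse chi-square, then
  # coefficients from their normal approximation, then residual noise
  s2 <- sum(fit$residuals^2) / df_res
  s2_star <- s2 * df_res / rchisq(1, df_res)
  V <- vcov(fit) * s2_star / s2
  b <- coef(fit)
  ok <- !is.na(b)
  b_star <- b
  b_star[ok] <- b[ok] + as.numeric(t(chol(V[ok, ok, drop = FALSE])) %*%
                                     rnorm(sum(ok)))
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)), newdata)
  mu <- as.numeric(mm[, ok, drop = FALSE] %*% b_star[ok])
  mu + rnorm(length(mu), 0, sqrt(s2_star))
}

draw_glm <- function(fit, newdata) {
  b <- coef(fit)
  ok <- !is.na(b)
  V <- vcov(fit)
  b_star <- b
  b_star[ok] <- b[ok] + as.numeric(t(chol(V[ok, ok, drop = FALSE])) %*%
                                     rnorm(sum(ok)))
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)), newdata)
  p <- plogis(as.numeric(mm[, ok, drop = FALSE] %*% b_star[ok]))
  rbinom(length(p), 1L, p)
}

draw_multinom <- function(fit, newdata, labels) {
  p <- predict(fit, newdata = newdata, type = "probs")
  if (is.null(dim(p))) {
    # multinom returns a bare vector for a single row (all classes) and for
    # the two-class case (probability of the second class)
    p <- if (length(labels) > 2 && nrow(newdata) == 1) matrix(p, nrow = 1)
    else cbind(1 - p, p)
  }
  apply(p, 1, function(pr) sample(labels, 1, prob = pmax(pr, 0)))
}

fit_conditional <- function(v, meta_v, frame, observed) {
  if (sum(observed) == 0)
    stop_sm("conditional imputation model for '%s' has zero usable rows", v)
  dat <- frame[observed, , drop = FALSE]
  if (meta_v$kind == "continuous") {
    y <- dat$.y
    log_scale <- all(y > 0)
    dat$.y <- if (log_scale) log(y) else y
    fit <- lm(.y ~ ., data = dat)
    list(kind = "continuous", fit = fit, log_scale = log_scale,
         df_res = fit$df.residual, range = range(y))
  } else if (meta_v$kind == "binary") {
    fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
    list(kind = "binary", fit = fit)
  } else {
    fit <- nnet::multinom(.y ~ ., data = dat, trace = FALSE)
    list(kind = "categorical", fit = fit, labels = meta_v$labels)
  }
}

draw_conditional <- function(model, frame, rows) {
  nd <- frame[rows, , drop = FALSE]
  nd$.y <- NULL
  if (model$kind == "continuous") {
    out <- draw_lm(model$fit, nd, model$df_res)
    if (model$log_scale) out <- exp(out)
    # clamp to the observed training range: chained draws through several
    # conditional models can otherwise cascade to extreme values
    pmin(pmax(out, model$range[1]), model$range[2])
  } else if (model$kind == "binary") {
    draw_glm(model$fit, nd)
  } else {
    draw_multinom(model$fit, nd, model$labels)
  }
}

#' Multiple imputation by chained equations
#'
#' A chained-equations imputer: iterative per-variable conditional models
#' (linear regression on the log scale for positive continuous variables,
#' logistic for binary, multinomial for categorical), cycled from a
#' random-draw initialisation. Predictors are the expert-source covariates
#' plus the Nelson--Aalen cumulative-hazard estimate at each patient's
#' follow-up time and the event flag; imputed draws include parameter and
#' residual noise, and continuous values are exponentiated back to their
#' original scale. `m` independent completions are produced, each carrying
#' its final-cycle conditional models so the fitted imputer can be applied
#' to held-out data without refitting (no training/test leakage).
#'
#' @param cohort a `cohort` (typically the training split).
#' @param m number of completed datasets (default 5).
#' @param n_cycles chained-equation cycles (default 10).
#' @param seed integer seed.
#' @return a `chained_imputation`: `completions` (list of `m` complete
#'   cohorts), `models` (per completion, per variable), `base_hazard`
#'   (training Nelson--Aalen, used to build predictors for new data),
#'   `predictors`, `impute_vars`.
#' @export
chained_imputation <- function(cohort, m = 5, n_cycles = 10, seed = 1) {
  stopifnot(inherits(cohort, "cohort"), m >= 1, n_cycles >= 1)
  mf <- missing_fraction(cohort)
  impute_vars <- names(mf)[mf > 0]
  na_fit <- km_nelson_aalen(cohort$time, cohort$event)
  cumhaz <- km_eval(na_fit, cohort$time, "cumhaz")
  expert <- names(cohort$values)[vapply(cohort$meta, `[[`, character(1),
                                        "source") == "expert"]

  if (length(impute_vars) == 0) {
    return(structure(list(
      completions = replicate(m, cohort, simplify = FALSE),
      models = replicate(m, list(), simplify = FALSE),
      base_hazard = na_fit, predictors = expert, impute_vars = character(0),
      n_cycles = n_cycles, seed = seed), class = "chained_imputation"))
  }

  # impute in order of increasing missingness
  impute_vars <- impute_vars[order(mf[impute_vars])]
  completions <- vector("list", m)
  models <- vector("list", m)
  for (im in seq_len(m)) {
    comp <- with_seed(child_seed(seed, sprintf("mice:%d", im)), {
      vals <- cohort$values
      obs <- lapply(vals, function(x) !is.na(x))
      for (v in impute_vars) {
        pool <- vals[[v]][obs[[v]]]
        vals[[v]][!obs[[v]]] <- sample(pool, sum(!obs[[v]]), replace = TRUE)
      }
      fit_models <- list()
      for (cycle in seq_len(n_cycles)) {
        for (v in impute_vars) {
          predictors <- setdiff(expert, v)
          frame <- impute_predictor_frame(vals, cohort$meta, predictors,
                                          cumhaz, cohort$event)
          frame$.y <- vals[[v]]
          mod <- fit_conditional(v, cohort$meta[[v]], frame, obs[[v]])
          drawn <- draw_conditional(mod, frame, !obs[[v]])
          if (cohort$meta[[v]]$kind == "categorical")
            vals[[v]][!obs[[v]]] <- factor(drawn, levels = cohort$meta[[v]]$labels)
          else vals[[v]][!obs[[v]]] <- drawn
          if (cycle == n_cycles) fit_models[[v]] <- mod
        }
      }
      list(vals = vals, fit_models = fit_models)
    })
    out <- cohort
    out$values <- comp$vals
    completions[[im]] <- out
    models[[im]] <- comp$fit_models
  }
  structure(list(completions = completions, models = models,
                 base_hazard = na_fit, predictors = expert,
                 impute_vars = impute_vars, n_cycles = n_cycles, seed = seed),
            class = "chained_imputation")
}

#' Apply a fitted chained imputer to new data
#'
#' Missing cells in `cohort` are initialised by random draws from the
#' training completions' conditional models' response pools and cycled
#' through the stored final-cycle conditional models, so held-out data are
#' completed without ever refitting on them.
#'
#' @param imp a `chained_imputation`.
#' @param cohort a `cohort` to complete (e.g. the test split).
#' @param completion which completion's models to use (1..m).
#' @param seed integer seed.
#' @return a complete `cohort`.
#' @export
apply_imputation <- function(imp, cohort, completion = 1, seed = 1) {
  stopifnot(inherits(imp, "chained_imputation"), inherits(cohort, "cohort"))
  mods <- imp$models[[completion]]
  cumhaz <- km_eval(imp$base_hazard, cohort$time, "cumhaz")
  with_seed(child_seed(seed, sprintf("mice_apply:%d", completion)), {
    vals <- cohort$values
    obs <- lapply(vals, function(x) !is.na(x))
    for (v in imp$impute_vars) {
      nmis <- sum(!obs[[v]])
      if (nmis == 0) next
      pool <- vals[[v]][obs[[v]]]
      if (length(pool) == 0) pool <- imp$completions[[completion]]$values[[v]]
      vals[[v]][!obs[[v]]] <- sample(pool, nmis, replace = TRUE)
    }
    for (cycle in seq_len(imp$n_cycles)) {
      for (v in imp$impute_vars) {
        if (sum(!obs[[v]]) == 0) next
        predictors <- setdiff(imp$predictors, v)
        frame <- impute_predictor_frame(vals, cohort$meta, predictors,
                                        cumhaz, cohort$event)
        drawn <- draw_conditional(mods[[v]], frame, !obs[[v]])
        if (cohort$meta[[v]]$kind == "categorical")
          vals[[v]][!obs[[v]]] <- factor(drawn, levels = cohort$meta[[v]]$labels)
        else vals[[v]][!obs[[v]]] <- drawn
      }
    }
    out <- cohort
    out$values <- vals
    out
  })
}
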