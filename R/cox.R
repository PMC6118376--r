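#' Fit a Cox proportional hazards model by Newton--Raphson
#'
#' Maximises the log partial likelihood (Efron or Breslow handling of tied
#' event times) by damped Newton iterations with step-halving whenever a
#' step would decrease the likelihood. Standard errors come from the
#' inverse observed information. Exactly collinear columns raise an error
#' naming the offending column rather than being dropped silently, so
#' encoding bugs surface.
#'
#' @param design a `design_matrix` from [encode()], or a plain numeric
#'   matrix.
#' @param time positive follow-up times.
#' @param event 0/1 event indicator.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the score: iteration stops when
#'   `max|gradient|` falls below `tol` (absolute) or below `tol *
#'   |loglik|` (relative guard for large cohorts).
#' @return a `cox_fit`: `coef`, `se`, `descriptors`, `loglik`,
#'   `loglik_null`, `ties`, `convergence` (iterations, final gradient norm,
#'   converged flag), plus the sorted data needed for the Breslow baseline.
#' @export
fit_cox <- function(design, time, event, ties = c("efron", "breslow"),
                    max_iter = 100, tol = 1e-8) {
  ties <- match.arg(ties)
  x <- if (inherits(design, "design_matrix")) design$x else as.matrix(design)
  descriptors <- if (inherits(design, "design_matrix")) design$descriptors else
    data.frame(column = colnames(x) %||% paste0("x", seq_len(ncol(x))),
               variable = colnames(x) %||% paste0("x", seq_len(ncol(x))),
               encoding = "raw-zero-filled", level = NA_character_,
               stringsAsFactors = FALSE)
  if (is.null(colnames(x))) colnames(x) <- descriptors$column
  n <- length(time)
  stopifnot(nrow(x) == n, length(event) == n)
  if (sum(event) == 0) stop_sm("no events: partial likelihood undefined")
  if (any(!is.finite(x))) stop_sm("design matrix contains non-finite entries")

  # rank check: exactly collinear columns are an error, reported by name
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    stop_sm("collinear or degenerate design columns: %s",
            paste(bad, collapse = ", "))
  }

  ord <- order(time, decreasing = TRUE)
  xs <- x[ord, , drop = FALSE]
  ts <- time[ord]
  es <- as.integer(event[ord])
  efron <- ties == "efron"

  p <- ncol(x)
  beta <- rep(0, p)
  eta <- rep(0, n)
  d0 <- .cox_deriv_cpp(xs, eta, es, ts, efron, TRUE)
  ll <- d0$loglik
  ll_null <- ll
  g <- d0$grad
  H <- d0$hess
  iter <- 0
  converged <- max(abs(g)) < tol
  while (!converged && iter < max_iter) {
    iter <- iter + 1
    info <- -H
    step <- tryCatch(solve(info, g), error = function(e)
      stop_sm("singular information matrix (monotone separation?)"))
    fac <- 1
    repeat {
      beta_new <- beta + fac * step
      eta_new <- as.numeric(xs %*% beta_new)
      eta_new <- eta_new - mean(eta_new)
      d <- .cox_deriv_cpp(xs, eta_new, es, ts, efron, TRUE)
      if (is.finite(d$loglik) && d$loglik >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10)
        stop_sm("step-halving failed: monotone likelihood (separation?)")
    }
    beta <- beta_new
    ll <- d$loglik
    g <- d$grad
    H <- d$hess
    converged <- max(abs(g)) < max(tol, tol * abs(ll))
  }
  info <- -H
  vc <- tryCatch(solve(info), error = function(e) matrix(NA, p, p))
  se <- sqrt(pmax(diag(vc), 0))
  names(beta) <- names(se) <- colnames(x)

  structure(list(coef = beta, se = se, vcov = vc, descriptors = descriptors,
                 loglik = ll, loglik_null = ll_null, ties = ties,
                 convergence = list(iterations = iter,
                                    grad_norm = max(abs(g)),
                                    converged = converged),
                 sorted = list(x = xs, time = ts, event = es)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d coefficients, ties=%s, loglik=%.3f (%s, %d iter)\n",
              length(x$coef), x$ties, x$loglik,
              if (x$convergence$converged) "converged" else "NOT converged",
              x$convergence$iterations))
  invisible(x)
}

#' Breslow baseline cumulative hazard
#'
#' Increment `d_k / sum_{risk set} exp(lp)` at each distinct event time.
#' With all coefficients zero this reduces exactly to the Nelson--Aalen
#' estimator.
#'
#' @param fit a `cox_fit` (uses the data it was fitted on by default).
#' @param x optional design matrix rows, with `time`, `event`, to use other
#'   data.
#' @param time,event optional, paired with `x`.
#' @return a `breslow_baseline`: step function as `time` (distinct event
#'   times, ascending) and `cumhaz`.
#' @export
breslow_baseline <- function(fit, x = NULL, time = NULL, event = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  if (is.null(x)) {
    xs <- fit$sorted$x; ts <- fit$sorted$time; es <- fit$sorted$event
  } else {
    x <- if (inherits(x, "design_matrix")) x$x else as.matrix(x)
    if (nrow(x) != length(time) || length(time) != length(event))
      stop_sm("mismatched row counts")
    ord <- order(time, decreasing = TRUE)
    xs <- x[ord, , drop = FALSE]; ts <- time[ord]; es <- as.integer(event[ord])
  }
  w <- exp(as.numeric(xs %*% fit$coef))
  # ts descending: risk set for event time t is the prefix with time >= t
  s0 <- cumsum(w)
  ut <- unique(ts[es == 1])                      # descending
  last_idx <- vapply(ut, function(t) max(which(ts == t)), integer(1))
  d <- vapply(ut, function(t) sum(es[ts == t]), numeric(1))
  inc <- d / s0[last_idx]
  o <- order(ut)
  structure(list(time = ut[o], cumhaz = cumsum(inc[o])),
            class = "breslow_baseline")
}

baseline_at <- function(bl, t) {
  idx <- findInterval(t, bl$time)
  c(0, bl$cumhaz)[idx + 1]
}

#' Predicted absolute risk of death by a horizon
#'
#' `P(death <= t*) = 1 - exp(-Lambda0(t*) * exp(lp))` under the fitted Cox
#' model with its Breslow baseline.
#'
#' @param fit a `cox_fit`.
#' @param design design rows for the patients to score.
#' @param horizon time horizon `t*` (years).
#' @param baseline optionally a precomputed [breslow_baseline()].
#' @return risks in `[0, 1]`, monotone in the linear predictor.
#' @export
predict_risk <- function(fit, design, horizon, baseline = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  x <- if (inherits(design, "design_matrix")) design$x else as.matrix(design)
  bl <- baseline %||% breslow_baseline(fit)
  if (horizon > max(fit$sorted$time)) {
    warn_sm("horizon %.3g beyond last observed time %.3g; clamping",
            horizon, max(fit$sorted$time))
    horizon <- max(fit$sorted$time)
  }
  lp <- as.numeric(x %*% fit$coef)
  1 - exp(-baseline_at(bl, horizon) * exp(lp))
}

#' Linear predictor of a Cox fit
#'
#' @param fit a `cox_fit`.
#' @param design design rows.
#' @return numeric linear predictor `x %*% beta`.
#' @export
cox_lp <- function(fit, design) {
  x <- if (inherits(design, "design_matrix")) design$x else as.matrix(design)
  as.numeric(x %*% fit$coef)
}

#' Serialise a Cox fit to JSON
#'
#' Writes descriptors, coefficients with standard errors, the Breslow
#' baseline as (time, value) pairs, the ties method and the convergence
#' record.
#'
#' @param fit a `cox_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cox_fit <- function(fit, path) {
  bl <- breslow_baseline(fit)
  jsonlite::write_json(list(
    coef = as.list(fit$coef), se = as.list(fit$se),
    descriptors = fit$descriptors,
    baseline = list(time = bl$time, cumhaz = bl$cumhaz),
    ties = fit$ties, convergence = fit$convergence),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
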