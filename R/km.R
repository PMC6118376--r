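#' Kaplan--Meier and Nelson--Aalen estimators
#'
#' Nonparametric survival-curve and cumulative-hazard estimators over right-
#' censored data. These are used throughout the package: as forest leaf
#' hazards, as an imputation predictor, for the age-only baseline model and
#' for missing-vs-present survival comparisons.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicator (1 = died).
#' @return a list with class `km_na`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv` (Kaplan--Meier S(t)), `cumhaz`
#'   (Nelson--Aalen cumulative hazard).
#' @export
km_nelson_aalen <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time[event == 1])
  n <- length(time)
  # at-risk just before each event time; data sorted ascending
  n_risk <- n - findInterval(ut, time, left.open = TRUE)
  n_event <- tabulate(match(time[event == 1], ut), nbins = length(ut))
  surv <- cumprod(1 - n_event / n_risk)
  cumhaz <- cumsum(n_event / n_risk)
  structure(list(time = ut, n_risk = n_risk, n_event = n_event,
                 surv = surv, cumhaz = cumhaz),
            class = "km_na")
}

#' Evaluate a right-continuous step function
#'
#' @param fit a `km_na` object (or any list with `time` and the requested
#'   component).
#' @param t times at which to evaluate.
#' @param what `"surv"` or `"cumhaz"`.
#' @return values at `t`; before the first event time, survival is 1 and the
#'   cumulative hazard 0.
#' @export
km_eval <- function(fit, t, what = c("surv", "cumhaz")) {
  what <- match.arg(what)
  idx <- findInterval(t, fit$time)
  init <- if (what == "surv") 1 else 0
  vals <- c(init, fit[[what]])
  vals[idx + 1]
}
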