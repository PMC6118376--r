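#' Variable effect curve from a Cox fit
#'
#' For a continuous variable under indicator (or imputed-raw) encoding the
#' partial effect is the straight line `beta * z` on the standardised scale,
#' with a 95% band `beta*z +/- 1.96 * se(beta) * |z|` that is exactly zero
#' at the baseline value `z = 0`; the companion missing-value coefficient
#' (when encoded) is returned as a separate point. For a discretised
#' variable the curve is one log-risk value per (bin or missing) category,
#' `beta_j +/- 1.96 * se_j`, with the lowest bin the zero-uncertainty
#' baseline.
#'
#' @param fit a `cox_fit`.
#' @param enc the `encoder` that produced the fit's design.
#' @param variable variable name.
#' @param values optional observed values used to set the grid range
#'   (defaults to +/- 2.5 standardised units).
#' @param grid_size grid points for continuous curves (default 50).
#' @return an `effect_curve`: `variable`, `model` (`"cox-continuous"` or
#'   `"cox-discrete"`), `curve` (x/level, central, lower, upper),
#'   `missing_point` (estimate, lower, upper) or `NULL`, `baseline`.
#' @export
cox_effect <- function(fit, enc, variable, values = NULL, grid_size = 50) {
  stopifnot(inherits(fit, "cox_fit"))
  d <- fit$descriptors
  rows <- d[d$variable == variable, , drop = FALSE]
  if (nrow(rows) == 0) stop_sm("variable '%s' not in the fit", variable)
  info <- enc$vars[[variable]]
  z95 <- qnorm(0.975)
  miss_col <- rows$column[rows$encoding %in% c("missing-indicator",
                                               "missing-dummy")]
  missing_point <- if (length(miss_col) == 1) {
    b <- fit$coef[[miss_col]]; s <- fit$se[[miss_col]]
    c(estimate = b, lower = b - z95 * s, upper = b + z95 * s)
  } else NULL

  if (!is.null(info) && info$kind == "continuous") {
    col <- rows$column[rows$encoding == "raw-zero-filled"]
    b <- fit$coef[[col]]; s <- fit$se[[col]]
    zr <- if (is.null(values)) c(-2.5, 2.5) else
      range((values[!is.na(values)] - info$center) / info$scale)
    z <- seq(zr[1], zr[2], length.out = grid_size)
    curve <- data.frame(x = z * info$scale + info$center, z = z,
                        central = b * z,
                        lower = b * z - z95 * s * abs(z),
                        upper = b * z + z95 * s * abs(z))
    structure(list(variable = variable, model = "cox-continuous",
                   curve = curve, missing_point = missing_point,
                   baseline = info$center),
              class = "effect_curve")
  } else {
    dr <- rows[rows$encoding %in% c("bin-dummy", "category-dummy",
                                    "missing-dummy"), , drop = FALSE]
    ref <- if (!is.null(info$scheme)) info$scheme$labels[1] else
      (enc$vars[[variable]]$levels %||% c("0"))[1]
    curve <- rbind(
      data.frame(level = ref, central = 0, lower = 0, upper = 0),
      data.frame(level = dr$level, central = unname(fit$coef[dr$column]),
                 lower = unname(fit$coef[dr$column] -
                                  z95 * fit$se[dr$column]),
                 upper = unname(fit$coef[dr$column] +
                                  z95 * fit$se[dr$column])))
    structure(list(variable = variable, model = "cox-discrete", curve = curve,
                   missing_point = missing_point, baseline = ref),
              class = "effect_curve")
  }
}

#' Partial dependence of a risk model on one variable
#'
#' Draws patients at random, sweeps the variable of interest over a grid of
#' observed-value quantiles while holding each patient's other variables
#' fixed, and predicts the risk at the horizon for every (patient, grid)
#' combination. Each patient's swept risk curve is normalised by its own
#' mean and logged (so 0 marks the patient's average risk over the sweep);
#' the central curve is the median across patients.
#'
#' @param risk_fun `function(cohort) -> risk` at the horizon (a forest,
#'   Cox model or any other risk model behind a closure).
#' @param cohort the cohort supplying patients and the variable's support.
#' @param variable variable to sweep.
#' @param n_patients patients sampled (default 1000).
#' @param grid_size grid points, equally spaced quantiles of the observed
#'   values (default 50).
#' @param seed integer seed.
#' @return an `effect_curve` with `curve` (x, central = median log
#'   normalised risk) and `patient_curves` (n_patients x grid matrix).
#' @export
partial_dependence <- function(risk_fun, cohort, variable, n_patients = 1000,
                               grid_size = 50, seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  x <- cohort$values[[variable]]
  if (is.null(x)) stop_sm("variable '%s' not in cohort", variable)
  obs <- as.numeric(x)[!is.na(x)]
  grid <- unique(quantile(obs, probs = seq(0, 1, length.out = grid_size),
                          names = FALSE))
  n <- length(cohort$time)
  take <- with_seed(child_seed(seed, "pd_sample"),
                    sample.int(n, min(n_patients, n)))
  base <- cohort_subset(cohort, take)
  G <- length(grid)
  m <- length(take)
  # one expanded cohort: patients repeated per grid value
  rep_idx <- rep(seq_len(m), times = G)
  expanded <- base
  expanded$patient_id <- sprintf("%s_g%03d", base$patient_id[rep_idx],
                                 rep(seq_len(G), each = m))
  expanded$time <- base$time[rep_idx]
  expanded$event <- base$event[rep_idx]
  expanded$values <- base$values[rep_idx, , drop = FALSE]
  expanded$values[[variable]] <- rep(grid, each = m)
  risks <- matrix(risk_fun(expanded), m, G)
  risks <- pmax(risks, 1e-12)
  lognorm <- log(risks / rowMeans(risks))
  structure(list(variable = variable, model = "partial-dependence",
                 curve = data.frame(x = grid,
                                    central = apply(lognorm, 2, median)),
                 patient_curves = lognorm, grid = grid),
            class = "effect_curve")
}

#' Survival curves for patients with versus without a recorded value
#'
#' Kaplan--Meier curves of the present and missing groups for one variable,
#' with the two-group logrank statistic and a summary of which group fares
#' worse at the horizon. Requires at least `min_group` patients in each
#' group.
#'
#' @param cohort a `cohort`.
#' @param variable variable name.
#' @param horizon horizon in years for the sign summary.
#' @param min_group minimum group size (default 20).
#' @return list: `km_present`, `km_missing`, `logrank`, `worse_when_missing`
#'   (TRUE when the missing group has lower survival at the horizon),
#'   `n_present`, `n_missing`.
#' @export
missingness_curves <- function(cohort, variable, horizon, min_group = 20) {
  x <- cohort$values[[variable]]
  if (is.null(x)) stop_sm("variable '%s' not in cohort", variable)
  miss <- is.na(x)
  if (!any(miss) || all(miss))
    stop_sm("comparison undefined: variable '%s' needs both present and missing patients",
            variable)
  if (sum(miss) < min_group || sum(!miss) < min_group)
    stop_sm("group too small for '%s' (present %d, missing %d, need >= %d)",
            variable, sum(!miss), sum(miss), min_group)
  km_p <- km_nelson_aalen(cohort$time[!miss], cohort$event[!miss])
  km_m <- km_nelson_aalen(cohort$time[miss], cohort$event[miss])
  lr <- logrank_statistic(cohort$time, cohort$event, as.integer(miss))
  s_p <- km_eval(km_p, horizon, "surv")
  s_m <- km_eval(km_m, horizon, "surv")
  list(km_present = km_p, km_missing = km_m, logrank = lr,
       worse_when_missing = s_m < s_p, n_present = sum(!miss),
       n_missing = sum(miss))
}

#' Write an effect curve as CSV
#'
#' @param effect an `effect_curve`.
#' @param path output path.
#' @return the data frame, invisibly.
#' @export
write_effect_curve <- function(effect, path) {
  df <- data.frame(variable = effect$variable, model = effect$model,
                   effect$curve)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
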