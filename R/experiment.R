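#' Experiment configuration for the model-comparison grid
#'
#' @param cohort a `synthetic_spec` (generated at run time), a `cohort`, or
#'   a path to a cohort CSV written by [write_cohort()].
#' @param entries list of grid entries; each a list with `name`, `model`
#'   (`"cox"`, `"rsf"`, `"coxnet"`, `"age-baseline"`), `encoding`
#'   (`"indicator"`, `"discrete"`, `"imputed"`, `"imputed-discrete"`,
#'   `"complete-case"`, `"raw"`), `variables` (`"expert"`, `"extended"` or a
#'   character vector), optional `selection` (list: `method`, `counts`,
#'   `k`), optional `params` (model parameters, e.g. a [forest_params()] or
#'   `list(alpha =, k =, m =)`).
#' @param horizon evaluation horizon in years (default 5).
#' @param B bootstrap replicates (default 200).
#' @param train_fraction training fraction (default 2/3).
#' @param n_bins bins for discretised encodings (default 10).
#' @param seed master seed.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(cohort, entries, horizon = 5, B = 200,
                              train_fraction = 2 / 3, n_bins = 10, seed = 1) {
  if (horizon <= 0) stop_sm("horizon must be positive")
  supported <- list(cox = c("indicator", "discrete", "imputed",
                            "imputed-discrete", "complete-case"),
                    rsf = c("raw", "imputed"),
                    coxnet = "discrete",
                    `age-baseline` = "raw")
  for (e in entries) {
    if (is.null(supported[[e$model]]) ||
        !(e$encoding %||% "raw") %in% supported[[e$model]])
      stop_sm("unsupported (model, encoding) pair: (%s, %s)",
              e$model, e$encoding %||% "raw")
  }
  structure(list(cohort = cohort, entries = entries, horizon = horizon,
                 B = B, train_fraction = train_fraction, n_bins = n_bins,
                 seed = seed),
            class = "experiment_config")
}

resolve_variables <- function(cohort, variables) {
  if (is.null(variables) || identical(variables, "extended"))
    return(names(cohort$values))
  if (identical(variables, "expert")) {
    src <- vapply(cohort$meta, `[[`, character(1), "source")
    return(names(cohort$values)[src == "expert"])
  }
  variables
}

# a model factory closure for one grid entry: (train, variables) -> predict
entry_factory <- function(entry, config) {
  horizon <- config$horizon
  n_bins <- config$n_bins
  model <- entry$model
  encoding <- entry$encoding %||% "raw"
  params <- entry$params %||% list()
  seed <- child_seed(config$seed, paste0("entry:", entry$name))

  function(train, variables) {
    tr <- cohort_subset(train, variables = variables)
    if (model == "cox" && encoding %in% c("indicator", "discrete")) {
      strat <- if (encoding == "indicator") "indicator" else "discrete-onehot"
      enc <- fit_encoder(tr, strat, n_bins = n_bins)
      fit <- fit_cox(encode(enc, tr), tr$time, tr$event)
      bl <- breslow_baseline(fit)
      function(new) predict_risk(fit, encode(enc, cohort_subset(
        new, variables = variables)), horizon, baseline = bl)
    } else if (model == "cox" && encoding == "complete-case") {
      # the traditional-analysis control: discard mostly-missing variables
      # entirely, then drop any row still missing a value
      usable <- names(tr$values)[missing_fraction(tr) <= 0.5]
      if (length(usable) == 0) stop_sm("no variables usable complete-case")
      tr <- cohort_subset(tr, variables = usable)
      variables <- usable
      keep <- !Reduce(`|`, c(lapply(tr$values, is.na), list(logical(length(tr$time)))))
      if (sum(keep) < 50) stop_sm("complete-case training set too small")
      cc <- cohort_subset(tr, keep)
      enc <- fit_encoder(cc, "indicator", na_fallback = TRUE)
      fit <- fit_cox(encode(enc, cc), cc$time, cc$event)
      bl <- breslow_baseline(fit)
      # held-out missing cells fall back to the training mean (z = 0)
      function(new) predict_risk(fit, encode(enc, cohort_subset(
        new, variables = variables)), horizon, baseline = bl)
    } else if (model == "cox" && encoding %in% c("imputed",
                                                 "imputed-discrete")) {
      m <- params$m %||% 5
      imp <- chained_imputation(tr, m = m, seed = seed)
      strat <- if (encoding == "imputed") "imputed-raw" else
        "imputed-discrete-onehot"
      fits <- lapply(imp$completions, function(comp) {
        enc <- fit_encoder(comp, strat, n_bins = n_bins)
        fit <- fit_cox(encode(enc, comp), comp$time, comp$event)
        list(enc = enc, fit = fit, bl = breslow_baseline(fit))
      })
      function(new) {
        nv <- cohort_subset(new, variables = variables)
        risks <- vapply(seq_len(m), function(i) {
          completed <- apply_imputation(imp, nv, completion = i, seed = seed)
          predict_risk(fits[[i]]$fit, encode(fits[[i]]$enc, completed),
                       horizon, baseline = fits[[i]]$bl)
        }, numeric(length(nv$time)))
        rowMeans(matrix(risks, ncol = m))
      }
    } else if (model == "rsf" && encoding == "raw") {
      fp <- do.call(forest_params, params[names(params) %in%
        c("n_trees", "mtry", "nsplit", "min_node_size",
          "n_impute_iterations")])
      forest <- fit_forest(tr, fp, seed = seed)
      function(new) forest_predict(forest, cohort_subset(
        new, variables = variables), horizon, seed = seed)
    } else if (model == "rsf" && encoding == "imputed") {
      m <- params$m %||% 2
      imp <- chained_imputation(tr, m = m, seed = seed)
      fp <- do.call(forest_params, params[names(params) %in%
        c("n_trees", "mtry", "nsplit", "min_node_size",
          "n_impute_iterations")])
      forests <- lapply(imp$completions, fit_forest, params = fp, seed = seed)
      function(new) {
        nv <- cohort_subset(new, variables = variables)
        risks <- vapply(seq_len(m), function(i) {
          completed <- apply_imputation(imp, nv, completion = i, seed = seed)
          forest_predict(forests[[i]], completed, horizon, seed = seed)
        }, numeric(length(nv$time)))
        rowMeans(matrix(risks, ncol = m))
      }
    } else if (model == "coxnet") {
      enc <- fit_encoder(tr, "discrete-onehot", n_bins = n_bins)
      xtr <- encode(enc, tr)
      cv <- cv_lambda(xtr, tr$time, tr$event,
                      alpha = params$alpha %||% 0.9,
                      k = params$k %||% 10, seed = seed,
                      n_lambda = params$n_lambda %||% 100)
      pred <- function(new) coxnet_predict_risk(cv$path, cv$lambda_min, xtr,
                                                encode(enc, cohort_subset(
                                                  new, variables = variables)),
                                                horizon)
      attr(pred, "n_selected") <- cv$nonzero
      pred
    } else if (model == "age-baseline") {
      function(new) age_baseline(tr, new, horizon)$risk
    } else {
      stop_sm("unsupported (model, encoding) pair: (%s, %s)", model, encoding)
    }
  }
}

fit_entry <- function(entry, train, config) {
  factory <- entry_factory(entry, config)
  vars <- resolve_variables(train, entry$variables %||% "extended")
  if (!is.null(entry$selection)) {
    sel <- entry$selection
    ranking <- rank_variables(cohort_subset(train, variables = vars),
                              method = sel$method %||% "logrank",
                              seed = child_seed(config$seed,
                                                paste0("rank:", entry$name)))
    chosen <- select_count(ranking, sel$counts, factory, train,
                           k = sel$k %||% 3,
                           seed = child_seed(config$seed,
                                             paste0("select:", entry$name)))
    list(predict = chosen$model, n_variables = chosen$count,
         selection = chosen[c("count", "cv_curve", "variables")])
  } else {
    predict <- factory(train, vars)
    list(predict = predict,
         n_variables = attr(predict, "n_selected") %||% length(vars),
         selection = NULL)
  }
}

#' Run the model-comparison experiment grid
#'
#' Generates (or loads) the cohort, makes one train/test split shared by
#' every grid entry, fits each (model, encoding) combination on the
#' training data only — variable selection and hyperparameter
#' cross-validation included — then evaluates all entries on the identical
#' test set with identical bootstrap replicate indices, so paired
#' differences are meaningful. Per-entry failures are recorded without
#' aborting the remaining entries.
#'
#' @param config an [experiment_config()].
#' @return an `experiment_report`: `entries` (per-entry C-index and
#'   calibration estimates and variable counts), `pairs` (pairwise paired
#'   bootstrap C-index differences with 95% intervals), `risks` (test-set
#'   risk matrix), `errors` (per-entry error messages), `test` outcome,
#'   `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- config$cohort
  if (inherits(cohort, "synthetic_spec")) cohort <- generate_cohort(cohort)$cohort
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "cohort"))

  sp <- split_train_test(cohort, config$train_fraction, seed = config$seed)
  train <- sp$train
  test <- sp$test
  n_test <- length(test$time)
  idx <- bootstrap_indices(n_test, config$B, config$seed)

  risks <- list()
  errors <- list()
  details <- list()
  for (entry in config$entries) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      fitted <- fit_entry(entry, train, config)
      r <- fitted$predict(test)
      stopifnot(length(r) == n_test)
      list(risk = r, n_variables = fitted$n_variables,
           selection = fitted$selection)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[entry$name]] <- conditionMessage(res)
      message(sprintf("[experiment] entry '%s' FAILED: %s", entry$name,
                      conditionMessage(res)))
    } else {
      risks[[entry$name]] <- res$risk
      details[[entry$name]] <- res[c("n_variables", "selection")]
      message(sprintf("[experiment] entry '%s' done (%.1fs)", entry$name,
                      proc.time()[["elapsed"]] - t0))
    }
  }

  ests <- list()
  rows <- list()
  for (nm in names(risks)) {
    ec <- bootstrap_performance(risks[[nm]], test$time, test$event, "c_index",
                                config$horizon, config$B, config$seed,
                                indices = idx)
    ecal <- tryCatch(
      bootstrap_performance(risks[[nm]], test$time, test$event, "calibration",
                            config$horizon, config$B, config$seed,
                            indices = idx),
      error = function(e) NULL)
    ests[[paste0(nm, ":c_index")]] <- ec
    if (!is.null(ecal)) ests[[paste0(nm, ":calibration")]] <- ecal
    rows[[nm]] <- data.frame(
      name = nm, n_variables = details[[nm]]$n_variables,
      c_index = ec$point, c_index_median = ec$median,
      c_index_lower = ec$lower, c_index_upper = ec$upper,
      calibration = if (is.null(ecal)) NA else ecal$point,
      calibration_median = if (is.null(ecal)) NA else ecal$median,
      calibration_lower = if (is.null(ecal)) NA else ecal$lower,
      calibration_upper = if (is.null(ecal)) NA else ecal$upper,
      stringsAsFactors = FALSE)
  }

  pair_rows <- list()
  nms <- names(risks)
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      da <- ests[[paste0(nms[i], ":c_index")]]$replicates -
        ests[[paste0(nms[j], ":c_index")]]$replicates
      qs <- quantile(da, c(0.025, 0.5, 0.975), na.rm = TRUE, names = FALSE)
      pair_rows[[length(pair_rows) + 1]] <- data.frame(
        a = nms[i], b = nms[j], median_diff = qs[2], lower = qs[1],
        upper = qs[3], stringsAsFactors = FALSE)
    }
  }

  structure(list(
    entries = if (length(rows)) do.call(rbind, rows) else
      data.frame(name = character(0)),
    pairs = if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame(a = character(0)),
    estimates = ests, risks = risks, errors = errors, details = details,
    test = list(time = test$time, event = test$event),
    n_failed = length(errors), config = config),
    class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d entries (%d failed), B=%d\n",
              nrow(x$entries), x$n_failed, x$config$B))
  if (nrow(x$entries)) {
    df <- x$entries
    cat(sprintf("  %-24s C=%.3f (%.3f-%.3f)  cal=%.3f\n", df$name,
                df$c_index, df$c_index_lower, df$c_index_upper,
                df$calibration), sep = "")
  }
  invisible(x)
}

#' Write an experiment report to a directory
#'
#' Emits `entries.csv`, `pairs.csv` and `report.json`.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$entries, file.path(dir, "entries.csv"), row.names = FALSE)
  write.csv(report$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  jsonlite::write_json(list(entries = report$entries, pairs = report$pairs,
                            errors = report$errors),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
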