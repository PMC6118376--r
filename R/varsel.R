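logrank_groups <- function(x, kind, time, event, missing_group_min = 0.01) {
  miss <- is.na(x)
  g <- if (kind == "continuous") {
    q <- quantile(x[!miss], probs = c(0.25, 0.5, 0.75), names = FALSE)
    cut(as.numeric(x), breaks = c(-Inf, unique(q), Inf), right = FALSE)
  } else factor(x)
  g <- as.character(g)
  if (mean(miss) >= missing_group_min) g[miss] <- ".missing"
  keep <- !is.na(g)
  list(group = g[keep], time = time[keep], event = event[keep])
}

#' Rank cohort variables for selection
#'
#' Three univariate rankings:
#' \describe{
#'   \item{missingness}{score = completeness (1 - missing fraction); the
#'     least missing variable ranks first.}
#'   \item{logrank}{score = the logrank statistic across the variable's
#'     groups: 0/1 for binary, the categories for categoricals, quartiles of
#'     the non-missing values for continuous variables -- with the missing
#'     cells as an extra group whenever at least 1% are missing (absence
#'     itself can carry prognosis).}
#'   \item{permutation}{score = mean drop in C-index over `n_shuffles`
#'     random within-column shuffles, for a fitted model evaluated through
#'     `risk_fun` on this (held-out) cohort.}
#' }
#' Rankings are permutation-invariant to input column order; ties are broken
#' by variable name.
#'
#' @param cohort a `cohort`.
#' @param method `"missingness"`, `"logrank"` or `"permutation"`.
#' @param risk_fun for `"permutation"`: `function(cohort) -> risk scores`.
#' @param n_shuffles shuffles per variable for permutation importance.
#' @param seed integer seed.
#' @param missing_group_min minimum missing fraction for a missing logrank
#'   group (default 0.01).
#' @return a `variable_ranking`: data frame (`rank`, `variable`, `score`),
#'   plus `method` and scoring metadata.
#' @export
rank_variables <- function(cohort, method = c("missingness", "logrank",
                                              "permutation"),
                           risk_fun = NULL, n_shuffles = 20, seed = 1,
                           missing_group_min = 0.01) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "cohort"))
  vars <- names(cohort$values)
  score <- setNames(numeric(length(vars)), vars)
  if (method == "missingness") {
    score <- 1 - missing_fraction(cohort)
  } else if (method == "logrank") {
    for (v in vars) {
      x <- cohort$values[[v]]
      if (all(is.na(x))) {
        warn_sm("variable '%s' entirely missing; ranked last", v)
        score[v] <- -Inf
        next
      }
      gr <- logrank_groups(x, cohort$meta[[v]]$kind, cohort$time,
                           cohort$event, missing_group_min)
      score[v] <- if (length(unique(gr$group)) < 2) 0 else
        logrank_statistic(gr$time, gr$event, gr$group)
    }
  } else {
    if (is.null(risk_fun))
      stop_sm("permutation ranking requires a fitted model's risk_fun")
    base_c <- c_index(risk_fun(cohort), cohort$time, cohort$event)
    for (v in vars) {
      drops <- with_seed(child_seed(seed, paste0("perm:", v)), {
        vapply(seq_len(n_shuffles), function(s) {
          shuffled <- cohort
          shuffled$values[[v]] <- sample(shuffled$values[[v]])
          base_c - c_index(risk_fun(shuffled), cohort$time, cohort$event)
        }, numeric(1))
      })
      score[v] <- mean(drops)
    }
  }
  o <- order(-score, vars)
  structure(list(ranking = data.frame(rank = seq_along(vars),
                                      variable = vars[o],
                                      score = unname(score[o]),
                                      stringsAsFactors = FALSE),
                 method = method,
                 meta = list(n_shuffles = if (method == "permutation")
                   n_shuffles else NULL,
                   missing_group_min = missing_group_min)),
            class = "variable_ranking")
}

#' Choose how many top-ranked variables to keep by cross-validated C-index
#'
#' For each candidate count, a model is fitted on k-1 folds using the
#' top-ranked variables and scored by C-index on the held-out fold; the
#' count with the best mean CV C-index wins and the final model is refitted
#' on the full training cohort with that many variables.
#'
#' @param ranking a `variable_ranking` on the training cohort.
#' @param counts candidate variable counts, descending (values above the
#'   ranking length are clamped).
#' @param model_factory `function(train_cohort, variables)` returning a
#'   `function(new_cohort) -> risk scores`.
#' @param train training `cohort`.
#' @param k folds (default 3).
#' @param seed integer seed.
#' @return list: `count` (chosen), `variables`, `cv_curve` (count, mean_c,
#'   se), `model` (refit on full training data).
#' @export
select_count <- function(ranking, counts, model_factory, train, k = 3,
                         seed = 1) {
  stopifnot(inherits(ranking, "variable_ranking"))
  counts <- sort(unique(pmin(counts, nrow(ranking$ranking))),
                 decreasing = TRUE)
  folds <- make_cv_folds(length(train$time), k, seed)
  rows <- list()
  for (ct in counts) {
    vars <- head(ranking$ranking$variable, ct)
    cs <- vapply(seq_len(k), function(f) {
      tr <- cohort_subset(train, folds != f, vars)
      te <- cohort_subset(train, folds == f, vars)
      predict_fun <- model_factory(tr, vars)
      c_index(predict_fun(te), te$time, te$event)
    }, numeric(1))
    rows[[as.character(ct)]] <- data.frame(count = ct, mean_c = mean(cs),
                                           se = sd(cs) / sqrt(k))
  }
  curve <- do.call(rbind, rows)
  best <- curve$count[which.max(curve$mean_c)]
  vars <- head(ranking$ranking$variable, best)
  list(count = best, variables = vars, cv_curve = curve,
       model = model_factory(cohort_subset(train, variables = vars), vars))
}

#' Write a variable ranking as CSV
#'
#' @param ranking a `variable_ranking`.
#' @param path output path.
#' @return the data frame, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(ranking$ranking, method = ranking$method)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
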