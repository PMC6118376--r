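#' Fit a quantile discretisation scheme for one continuous variable
#'
#' Bin edges are empirical quantiles of the non-missing values, giving bins
#' of (near-)equal occupancy on the fitting sample; a dedicated extra
#' category receives missing cells when the scheme is applied. Tied values
#' can collapse duplicate edges, reducing the effective bin count (recorded).
#'
#' @param values numeric vector (may contain `NA`).
#' @param n_bins requested bin count, between `bin_range[1]` and
#'   `bin_range[2]` (default 10--20).
#' @param variable variable name, used in error messages and the scheme.
#' @param bin_range permitted range for `n_bins`.
#' @return a `discretisation_scheme`: `variable`, `breaks` (strictly
#'   increasing interior edges), `n_bins` (effective), `n_requested`,
#'   `labels` (bin labels plus `"missing"`), `missing_label`.
#' @export
fit_discretisation <- function(values, n_bins = 10, variable = "x",
                               bin_range = c(10L, 20L)) {
  if (n_bins < bin_range[1] || n_bins > bin_range[2])
    stop_sm("n_bins must lie in [%d, %d]", bin_range[1], bin_range[2])
  x <- values[!is.na(values)]
  if (length(x) == 0) stop_sm("variable '%s' is entirely missing", variable)
  if (length(unique(x)) < 2)
    stop_sm("degenerate variable '%s': no quantile structure", variable)
  breaks <- unique(quantile(x, probs = seq_len(n_bins - 1) / n_bins,
                            names = FALSE, type = 7))
  eff <- length(breaks) + 1L
  if (eff < 2L)
    stop_sm("variable '%s' has too few distinct values for %d bins",
            variable, n_bins)
  labels <- sprintf("bin%02d", seq_len(eff))
  structure(list(variable = variable, breaks = breaks, n_bins = eff,
                 n_requested = as.integer(n_bins),
                 labels = labels, missing_label = "missing"),
            class = "discretisation_scheme")
}

#' Apply a discretisation scheme
#'
#' Bin membership uses half-open intervals `[edge_k, edge_{k+1})` with the
#' last bin closed above; values below or above the fitted range clamp to
#' the first or last bin; missing cells map to the dedicated missing
#' category (the scheme's extra, highest-index category).
#'
#' @param values numeric vector.
#' @param scheme a `discretisation_scheme` fitted on training data.
#' @return a factor with levels `c(bin labels, "missing")`.
#' @export
apply_discretisation <- function(values, scheme) {
  stopifnot(inherits(scheme, "discretisation_scheme"))
  idx <- findInterval(values, scheme$breaks) + 1L  # values == edge go right
  lab <- scheme$labels[idx]
  lab[is.na(values)] <- scheme$missing_label
  factor(lab, levels = c(scheme$labels, scheme$missing_label))
}

#' Fit an encoder mapping a cohort to a model design matrix
#'
#' Fitted on the training cohort only (quantile edges, standardisation
#' statistics, which variables carry missing values), then applied to any
#' cohort by [encode()]. Strategies:
#' \describe{
#'   \item{indicator}{continuous variables standardised by training
#'     mean/SD, zero-filled where missing, with a paired 0/1 missingness
#'     indicator column added only for variables that have at least one
#'     missing training value (so a missing value contributes exactly its
#'     own coefficient to the linear predictor); categorical variables
#'     become reference-coded dummies plus a missing dummy when needed;
#'     binary variables stay 0/1 with the same indicator treatment.}
#'   \item{discrete-onehot}{every continuous variable is quantile-
#'     discretised and every (bin or missing) category except the lowest
#'     bin becomes a 0/1 column; categoricals and binaries one-hot against
#'     their first level, plus a missing dummy when needed.}
#'   \item{imputed-raw}{like `indicator` but expects complete data and
#'     emits no indicator columns (errors on `NA`).}
#'   \item{imputed-discrete-onehot}{discretised one-hot over complete data,
#'     no missing category columns.}
#' }
#'
#' @param cohort training `cohort`.
#' @param strategy encoding strategy.
#' @param n_bins bins per continuous variable for discrete strategies.
#' @param bin_range permitted bin-count range.
#' @param na_fallback when `TRUE`, missing values met at apply time for
#'   variables that had none in training fall back to the reference level
#'   (all dummies zero / training mean) instead of erroring; used by
#'   complete-case comparators that must still score incomplete patients.
#' @return an `encoder` object.
#' @export
fit_encoder <- function(cohort,
                        strategy = c("indicator", "discrete-onehot",
                                     "imputed-raw", "imputed-discrete-onehot"),
                        n_bins = 10, bin_range = c(10L, 20L),
                        na_fallback = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cohort, "cohort"))
  discrete <- strategy %in% c("discrete-onehot", "imputed-discrete-onehot")
  imputed <- strategy %in% c("imputed-raw", "imputed-discrete-onehot")
  vars <- list()
  for (v in names(cohort$values)) {
    m <- cohort$meta[[v]]
    x <- cohort$values[[v]]
    has_missing <- anyNA(x) && !imputed
    if (imputed && anyNA(x))
      stop_sm("strategy '%s' requires complete data but '%s' has missing cells",
              strategy, v)
    if (m$kind == "continuous" && discrete) {
      vars[[v]] <- list(kind = "discrete",
                        scheme = fit_discretisation(x, n_bins, v, bin_range),
                        has_missing = has_missing)
    } else if (m$kind == "continuous") {
      xn <- x[!is.na(x)]
      if (length(xn) == 0) stop_sm("variable '%s' is entirely missing", v)
      s <- sd(xn)
      vars[[v]] <- list(kind = "continuous", center = mean(xn),
                        scale = if (is.na(s) || s == 0) 1 else s,
                        has_missing = has_missing)
    } else if (m$kind == "binary") {
      vars[[v]] <- list(kind = "binary", has_missing = has_missing)
    } else {
      lev <- m$labels %||% levels(x)
      vars[[v]] <- list(kind = "categorical", levels = lev,
                        has_missing = has_missing)
    }
  }
  structure(list(strategy = strategy, vars = vars,
                 variables = names(cohort$values),
                 na_fallback = na_fallback),
            class = "encoder")
}

#' Encode a cohort into a numeric design matrix
#'
#' @param enc an `encoder` fitted on the training split.
#' @param cohort a `cohort` (training or held-out).
#' @return a `design_matrix`: list with `x` (numeric matrix), `descriptors`
#'   (data frame: `column`, `variable`, `encoding`, `level`), and
#'   `reference` (named reference level per dummy-coded variable). Unseen
#'   categorical labels at apply time map to the missing category with a
#'   warning.
#' @export
encode <- function(enc, cohort) {
  stopifnot(inherits(enc, "encoder"), inherits(cohort, "cohort"))
  n <- length(cohort$time)
  cols <- list()
  desc <- list()
  refs <- character(0)
  add <- function(name, values, variable, encoding, level) {
    cols[[length(cols) + 1L]] <<- setNames(list(values), name)
    desc[[length(desc) + 1L]] <<- data.frame(column = name, variable = variable,
                                             encoding = encoding, level = level,
                                             stringsAsFactors = FALSE)
  }
  for (v in enc$variables) {
    if (!v %in% names(cohort$values))
      stop_sm("variable '%s' absent from cohort", v)
    info <- enc$vars[[v]]
    x <- cohort$values[[v]]
    if (info$kind == "continuous") {
      z <- (as.numeric(x) - info$center) / info$scale
      z[is.na(z)] <- 0
      add(v, z, v, "raw-zero-filled", NA_character_)
      if (info$has_missing)
        add(paste0(v, "_missing"), as.numeric(is.na(x)), v,
            "missing-indicator", NA_character_)
    } else if (info$kind == "binary") {
      z <- as.numeric(x)
      z[is.na(z)] <- 0
      if (enc$strategy %in% c("discrete-onehot", "imputed-discrete-onehot")) {
        add(paste0(v, "_1"), z, v, "category-dummy", "1")
        refs[v] <- "0"
      } else {
        add(v, z, v, "raw-zero-filled", NA_character_)
      }
      if (info$has_missing)
        add(paste0(v, "_missing"), as.numeric(is.na(x)), v,
            "missing-indicator", NA_character_)
    } else if (info$kind == "categorical") {
      lev <- info$levels
      xx <- as.character(x)
      unseen <- !is.na(xx) & !xx %in% lev
      if (any(unseen)) {
        warn_sm("variable '%s': %d unseen categor%s mapped to missing",
                v, sum(unseen), if (sum(unseen) == 1) "y" else "ies")
        xx[unseen] <- NA
      }
      refs[v] <- lev[1]
      for (l in lev[-1])
        add(paste0(v, "_", l), as.numeric(!is.na(xx) & xx == l), v,
            "category-dummy", l)
      if (info$has_missing)
        add(paste0(v, "_missing"), as.numeric(is.na(xx)), v,
            "missing-dummy", "missing")
      else if (anyNA(xx) && !isTRUE(enc$na_fallback))
        stop_sm("variable '%s' has missing values unseen in training", v)
    } else {  # discrete
      f <- apply_discretisation(as.numeric(x), info$scheme)
      lev <- levels(f)
      keep <- if (info$has_missing) lev[-1] else
        setdiff(lev[-1], info$scheme$missing_label)
      if (!info$has_missing && any(f == info$scheme$missing_label) &&
          !isTRUE(enc$na_fallback))
        stop_sm("variable '%s' has missing values unseen in training", v)
      refs[v] <- lev[1]
      for (l in keep)
        add(paste0(v, "_", l), as.numeric(f == l), v,
            if (l == info$scheme$missing_label) "missing-dummy" else "bin-dummy",
            l)
    }
  }
  x <- do.call(cbind, lapply(cols, `[[`, 1))
  colnames(x) <- vapply(cols, names, character(1))
  structure(list(x = x, descriptors = do.call(rbind, desc), reference = refs),
            class = "design_matrix")
}

#' Split a cohort into training and test sets
#'
#' @param cohort a `cohort`.
#' @param train_fraction fraction assigned to training (default 2/3).
#' @param seed integer seed; the split is reproducible.
#' @return list with `train` and `test` cohorts and the `train_idx`.
#' @export
split_train_test <- function(cohort, train_fraction = 2 / 3, seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_sm("train_fraction must lie strictly between 0 and 1")
  n <- length(cohort$time)
  n_train <- round(n * train_fraction)
  idx <- with_seed(child_seed(seed, "train_test_split"),
                   sample.int(n, n_train))
  idx <- sort(idx)
  list(train = cohort_subset(cohort, idx),
       test = cohort_subset(cohort, setdiff(seq_len(n), idx)),
       train_idx = idx)
}

#' Assign cross-validation folds
#'
#' @param n number of patients (or a `cohort`).
#' @param k number of folds (default 3).
#' @param seed integer seed.
#' @return integer vector of fold labels 1..k, sizes within one of `n/k`.
#' @export
make_cv_folds <- function(n, k = 3, seed = 1) {
  if (inherits(n, "cohort")) n <- length(n$time)
  if (k < 2) stop_sm("k must be at least 2")
  if (k > n) stop_sm("k exceeds the number of patients")
  with_seed(child_seed(seed, "cv_folds"),
            sample(rep_len(seq_len(k), n)))
}
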