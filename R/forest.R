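#' Logrank statistic across survival groups
#'
#' Standard observed-minus-expected logrank statistic on the chi-square
#' scale. For two groups it equals `(O - E)^2 / V` with the hypergeometric
#' variance; for k groups the quadratic form of the first k-1 group scores
#' with their covariance matrix.
#'
#' @param time follow-up times.
#' @param event 0/1 event indicator.
#' @param group group labels (factor, character or integer); at least two
#'   non-empty groups.
#' @return the chi-square-scale statistic (0 when the variance degenerates).
#' @export
logrank_statistic <- function(time, event, group) {
  g <- as.integer(factor(group))
  if (length(unique(g)) < 2) stop_sm("need at least two non-empty groups")
  if (sum(event) == 0) stop_sm("no events: logrank undefined")
  G <- max(g)
  o <- order(time)
  time <- time[o]; event <- event[o]; g <- g[o]
  ut <- unique(time[event == 1])
  K <- length(ut)
  n_k <- length(time) - findInterval(ut, time, left.open = TRUE)
  ngk <- matrix(0, K, G)
  dgk <- matrix(0, K, G)
  for (j in seq_len(G)) {
    tj <- time[g == j]
    ngk[, j] <- length(tj) - findInterval(ut, tj, left.open = TRUE)
    ev <- time[g == j & event == 1]
    dgk[, j] <- tabulate(match(ev, ut), nbins = K)
  }
  d_k <- rowSums(dgk)
  pk <- ngk / n_k
  z <- colSums(dgk - d_k * pk)[-G]
  w <- ifelse(n_k > 1, d_k * (n_k - d_k) / (n_k - 1), 0)
  V <- matrix(0, G - 1, G - 1)
  for (a in seq_len(G - 1)) for (b in a:(G - 1)) {
    V[a, b] <- V[b, a] <- sum(w * pk[, a] * ((a == b) - pk[, b]))
  }
  vi <- tryCatch(solve(V, z), error = function(e) NULL)
  if (is.null(vi)) {
    ev <- eigen(V, symmetric = TRUE)
    keep <- ev$values > max(ev$values, 0) * 1e-10
    if (!any(keep)) return(0)
    vi <- ev$vectors[, keep, drop = FALSE] %*%
      ((t(ev$vectors[, keep, drop = FALSE]) %*% z) / ev$values[keep])
  }
  max(sum(z * vi), 0)
}

#' Random survival forest parameters
#'
#' @param n_trees number of bootstrap trees (default 500).
#' @param mtry variables tried per split (default `floor(sqrt(p))`, resolved
#'   at fit time when `NULL`).
#' @param nsplit candidate split points per continuous variable (default 10);
#'   also caps the number of random label partitions tried for categoricals.
#' @param min_node_size minimum members per leaf (default 15).
#' @param n_impute_iterations routing refresh passes for the adaptive tree
#'   imputation of missing values (default 5).
#' @return a `forest_params` list.
#' @export
forest_params <- function(n_trees = 500, mtry = NULL, nsplit = 10,
                          min_node_size = 15, n_impute_iterations = 5) {
  stopifnot(n_trees >= 1, nsplit >= 1, min_node_size >= 1,
            n_impute_iterations >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 nsplit = as.integer(nsplit),
                 min_node_size = as.integer(min_node_size),
                 n_impute_iterations = as.integer(n_impute_iterations)),
            class = "forest_params")
}

# numeric working copy of the covariates: continuous/binary as numeric,
# categoricals as integer codes (labels kept aside)
forest_frame <- function(cohort) {
  vars <- names(cohort$values)
  cols <- list()
  kinds <- character(0)
  labels <- list()
  for (v in vars) {
    kind <- cohort$meta[[v]]$kind
    kinds[v] <- kind
    if (kind == "categorical") {
      f <- cohort$values[[v]]
      labels[[v]] <- levels(f)
      cols[[v]] <- as.integer(f)
    } else {
      cols[[v]] <- as.numeric(cohort$values[[v]])
    }
  }
  list(cols = cols, kinds = kinds, labels = labels, vars = vars)
}

# candidate splits for one variable within a node; x is the node's values
candidate_splits <- function(x, kind, nsplit) {
  obs <- x[!is.na(x)]
  if (kind == "categorical") {
    labs <- sort(unique(obs))
    if (length(labs) < 2) return(NULL)
    n_cand <- min(nsplit, 2^(length(labs) - 1) - 1)
    subsets <- list()
    tries <- 0
    while (length(subsets) < n_cand && tries < 20 * n_cand) {
      tries <- tries + 1
      take <- labs[runif(length(labs)) < 0.5]
      if (length(take) == 0 || length(take) == length(labs)) next
      # canonical form: the side containing the smallest label
      if (!labs[1] %in% take) take <- setdiff(labs, take)
      key <- paste(take, collapse = ",")
      if (!key %in% names(subsets)) subsets[[key]] <- take
    }
    if (length(subsets) == 0) return(NULL)
    list(kind = "categorical", sets = unname(subsets))
  } else {
    ux <- unique(obs)
    if (length(ux) < 2) return(NULL)
    # thresholds drawn uniformly from the node's observed values; splitting
    # at the maximum would put everything left, so exclude it
    ux <- setdiff(ux, max(ux))
    thr <- if (length(ux) <= nsplit) ux else sample(ux, nsplit)
    list(kind = "continuous", thresholds = thr)
  }
}

left_membership <- function(x, split) {
  if (split$kind == "categorical") x %in% split$set else x <= split$threshold
}

# route node members: non-missing by the split, missing at random weighted
# by the ratio of non-missing members sent to each branch (adaptive tree
# imputation); the routing draw is refreshed n_iter times and the last pass
# kept.
route_members <- function(x, split, n_iter) {
  obs <- !is.na(x)
  left <- logical(length(x))
  left[obs] <- left_membership(x[obs], split)
  ratio <- if (any(obs)) mean(left[obs]) else 0.5
  if (any(!obs)) {
    for (it in seq_len(n_iter)) draw <- runif(sum(!obs)) < ratio
    left[!obs] <- draw
  }
  list(left = left, ratio = ratio)
}

grow_node <- function(idx, frame, time, event, params, mtry) {
  n <- length(idx)
  n_ev <- sum(event[idx])
  make_leaf <- function() {
    list(type = "leaf", haz = km_nelson_aalen(time[idx], event[idx]), n = n)
  }
  if (n < 2 * params$min_node_size || n_ev == 0) return(make_leaf())

  vars <- sample(frame$vars, min(mtry, length(frame$vars)))
  tt <- time[idx]; ee <- event[idx]
  o <- order(tt)
  tt_s <- tt[o]; ee_s <- ee[o]

  best <- NULL; best_stat <- 0
  for (v in vars) {
    x <- frame$cols[[v]][idx]
    cand <- candidate_splits(x, frame$kinds[[v]], params$nsplit)
    if (is.null(cand)) next
    obs_s <- !is.na(x[o])
    xo <- x[o][obs_s]
    if (sum(obs_s) < 2 || sum(ee_s[obs_s]) == 0) next
    splits <- if (cand$kind == "categorical")
      lapply(cand$sets, function(s) list(kind = "categorical", set = s)) else
      lapply(cand$thresholds, function(t) list(kind = "continuous",
                                               threshold = t))
    memb <- vapply(splits, function(s) as.integer(left_membership(xo, s)),
                   integer(length(xo)))
    if (!is.matrix(memb)) memb <- matrix(memb, ncol = length(splits))
    ok <- colSums(memb) > 0 & colSums(memb) < nrow(memb)
    if (!any(ok)) next
    stats <- rep(-Inf, length(splits))
    stats[ok] <- .lr_scan_cpp(tt_s[obs_s], ee_s[obs_s],
                              memb[, ok, drop = FALSE])
    j <- which.max(stats)  # ties broken by first-drawn candidate
    if (stats[j] > best_stat) {
      best_stat <- stats[j]
      best <- c(splits[[j]], list(var = v))
    }
  }
  if (is.null(best)) return(make_leaf())

  routed <- route_members(frame$cols[[best$var]][idx], best,
                          params$n_impute_iterations)
  nl <- sum(routed$left)
  if (nl < params$min_node_size || (n - nl) < params$min_node_size)
    return(make_leaf())
  list(type = "split", var = best$var, kind = best$kind,
       threshold = best$threshold, set = best$set,
       ratio_left = routed$ratio, stat = best_stat,
       left = grow_node(idx[routed$left], frame, time, event, params, mtry),
       right = grow_node(idx[!routed$left], frame, time, event, params, mtry))
}

#' Grow a single survival tree
#'
#' At each node, `mtry` variables are drawn without replacement; for
#' continuous variables `nsplit` candidate thresholds are drawn uniformly
#' from the node's observed values, for categoricals up to `nsplit` random
#' binary label partitions. The candidate with the largest two-group logrank
#' statistic (computed over the node's non-missing members) is chosen;
#' missing values are then routed by adaptive tree imputation -- assigned at
#' random to a branch with probability equal to the ratio of non-missing
#' members sent to that branch, the draw refreshed over
#' `n_impute_iterations` passes. Leaves store the Nelson--Aalen cumulative
#' hazard of their members.
#'
#' @param cohort a `cohort` (typically a bootstrap sample).
#' @param params a [forest_params()].
#' @param seed integer seed.
#' @param frame internal precomputed numeric frame (optional).
#' @return a `survival_tree`.
#' @export
grow_tree <- function(cohort, params = forest_params(), seed = 1,
                      frame = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(cohort$time) == 0) stop_sm("empty sample")
  if (sum(cohort$event) == 0) stop_sm("sample has no events")
  frame <- frame %||% forest_frame(cohort)
  mtry <- params$mtry %||% max(1L, floor(sqrt(length(frame$vars))))
  root <- with_seed(seed, grow_node(seq_along(cohort$time), frame,
                                    cohort$time, cohort$event, params, mtry))
  structure(list(root = root, params = params, seed = seed,
                 vars = frame$vars, kinds = frame$kinds,
                 labels = frame$labels),
            class = "survival_tree")
}

# route rows of a frame down a tree; returns leaf assignment (list of row
# index vectors paired with leaves); missing values routed at random by the
# stored non-missing branch ratio
tree_leaves_for <- function(node, idx, cols) {
  if (node$type == "leaf") return(list(list(idx = idx, leaf = node)))
  x <- cols[[node$var]][idx]
  obs <- !is.na(x)
  left <- logical(length(idx))
  left[obs] <- left_membership(x[obs],
                               list(kind = node$kind, threshold = node$threshold,
                                    set = node$set))
  if (any(!obs)) left[!obs] <- runif(sum(!obs)) < node$ratio_left
  c(tree_leaves_for(node$left, idx[left], cols),
    tree_leaves_for(node$right, idx[!left], cols))
}

# per-row cumulative hazard of one tree at the requested times
tree_chf <- function(tree, cols, n, times) {
  out <- matrix(0, n, length(times))
  for (piece in tree_leaves_for(tree$root, seq_len(n), cols)) {
    ch <- km_eval(piece$leaf$haz, times, "cumhaz")
    out[piece$idx, ] <- matrix(ch, length(piece$idx), length(times),
                               byrow = TRUE)
  }
  out
}

#' Fit a random survival forest
#'
#' Bootstrap-resamples the training cohort for each tree and grows
#' logrank-split survival trees with adaptive tree imputation of missing
#' values (see [grow_tree()]). Tree seeds are derived deterministically from
#' the forest seed, so the result is independent of growth order.
#'
#' @param cohort training `cohort`.
#' @param params a [forest_params()].
#' @param seed integer seed.
#' @return a `survival_forest`.
#' @export
fit_forest <- function(cohort, params = forest_params(), seed = 1) {
  stopifnot(inherits(cohort, "cohort"))
  frame <- forest_frame(cohort)
  n <- length(cohort$time)
  trees <- lapply(seq_len(params$n_trees), function(b) {
    bs <- with_seed(child_seed(seed, sprintf("bootstrap:%d", b)),
                    sample.int(n, n, replace = TRUE))
    sub <- list(cols = lapply(frame$cols, `[`, bs), kinds = frame$kinds,
                labels = frame$labels, vars = frame$vars)
    boot_cohort <- cohort
    boot_cohort$time <- cohort$time[bs]
    boot_cohort$event <- cohort$event[bs]
    tr <- grow_tree_internal(boot_cohort$time, boot_cohort$event, sub, params,
                             child_seed(seed, sprintf("tree:%d", b)))
    tr
  })
  structure(list(trees = trees, params = params, seed = seed,
                 vars = frame$vars, kinds = frame$kinds, labels = frame$labels),
            class = "survival_forest")
}

grow_tree_internal <- function(time, event, frame, params, seed) {
  if (sum(event) == 0) {
    return(structure(list(root = list(type = "leaf",
                                      haz = km_nelson_aalen(time, event),
                                      n = length(time)),
                          params = params, seed = seed, vars = frame$vars,
                          kinds = frame$kinds, labels = frame$labels),
                     class = "survival_tree"))
  }
  mtry <- params$mtry %||% max(1L, floor(sqrt(length(frame$vars))))
  root <- with_seed(seed, grow_node(seq_along(time), frame, time, event,
                                    params, mtry))
  structure(list(root = root, params = params, seed = seed, vars = frame$vars,
                 kinds = frame$kinds, labels = frame$labels),
            class = "survival_tree")
}

#' Ensemble predictions from a survival forest
#'
#' The ensemble cumulative hazard function is the mean of the per-tree leaf
#' Nelson--Aalen hazards; predicted risk is `1 - exp(-CHF(t*))`.
#'
#' @param forest a `survival_forest`.
#' @param cohort a `cohort` to score.
#' @param times numeric vector of evaluation times (e.g. the 5-year horizon).
#' @param seed seed for the randomised routing of missing values.
#' @param type `"risk"` (`1 - exp(-CHF)`) or `"chf"`.
#' @return a matrix (patients x times), or a vector when `length(times)` is 1.
#' @export
forest_predict <- function(forest, cohort, times, seed = 1,
                           type = c("risk", "chf")) {
  type <- match.arg(type)
  stopifnot(inherits(forest, "survival_forest"), inherits(cohort, "cohort"))
  missing_vars <- setdiff(forest$vars, names(cohort$values))
  if (length(missing_vars))
    stop_sm("cohort lacks variables used in training: %s",
            paste(missing_vars, collapse = ", "))
  frame <- forest_frame(cohort_subset(cohort, variables = forest$vars))
  n <- length(cohort$time)
  acc <- matrix(0, n, length(times))
  with_seed(child_seed(seed, "forest_predict"), {
    for (tree in forest$trees) acc <- acc + tree_chf(tree, frame$cols, n, times)
  })
  chf <- acc / length(forest$trees)
  out <- if (type == "risk") 1 - exp(-chf) else chf
  if (length(times) == 1) as.numeric(out) else out
}

tree_depths <- function(node, d = 0) {
  if (node$type == "leaf") return(d)
  c(tree_depths(node$left, d + 1), tree_depths(node$right, d + 1))
}

tree_leaf_sizes <- function(node) {
  if (node$type == "leaf") return(node$n)
  c(tree_leaf_sizes(node$left), tree_leaf_sizes(node$right))
}

#' @export
print.survival_forest <- function(x, ...) {
  depths <- unlist(lapply(x$trees, function(t) max(tree_depths(t$root))))
  sizes <- unlist(lapply(x$trees, function(t) tree_leaf_sizes(t$root)))
  cat(sprintf(paste0("<survival_forest> %d trees over %d variables; depth ",
                     "median %.0f [%d, %d]; leaf size median %.0f\n"),
              length(x$trees), length(x$vars), median(depths), min(depths),
              max(depths), median(sizes)))
  invisible(x)
}
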