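# Honest causal forest on quantile-binned covariates.
#
# Each tree draws a subsample of the training data without replacement,
# splits it into a structure half (used to choose splits) and an estimation
# half (used to estimate leaf-level treatment-outcome associations), and
# recursively picks the (covariate, ordinal threshold) pair maximizing
# sum over children of n_child * tau_child^2, tau being the treated-minus-
# control event-rate difference. This maximization is algebraically the
# complement of minimizing the within-leaf squared error of a leaf-constant
# treatment-effect prediction, so high-scoring splits are exactly those
# that concentrate effect heterogeneity across leaves.

#' Forest hyperparameters
#'
#' @param n_trees Number of trees (default 1000).
#' @param subsample_fraction Fraction of the training data drawn without
#'   replacement for each tree (default 0.5).
#' @param structure_fraction Fraction of each tree's subsample used to
#'   choose splits; the remainder estimates leaf effects (default 0.5).
#' @param min_leaf_treated,min_leaf_control Minimum per-arm counts every
#'   child must retain in BOTH the structure and estimation halves for a
#'   split to be admissible (defaults 10).
#' @param max_depth Maximum tree depth (default 4; 0 = a single leaf).
#' @param honest If `TRUE` (default) leaf effects come from the estimation
#'   half only; if `FALSE` structure data estimate their own leaves.
#' @param subsample_is_structure If `TRUE`, the whole subsample is the
#'   structure half and the complement of the subsample within the
#'   training data is the estimation half, instead of halving the
#'   subsample (default `FALSE`).
#' @param seed Master seed; per-tree seeds are derived from it.
#' @return An object of class `forest_params`.
#' @export
forest_params <- function(n_trees = 1000L,
                          subsample_fraction = 0.5,
                          structure_fraction = 0.5,
                          min_leaf_treated = 10L,
                          min_leaf_control = 10L,
                          max_depth = 4L,
                          honest = TRUE,
                          subsample_is_structure = FALSE,
                          seed = 1L) {
  stopifnot(
    n_trees >= 1,
    subsample_fraction > 0, subsample_fraction < 1,
    structure_fraction > 0, structure_fraction < 1,
    min_leaf_treated >= 1, min_leaf_control >= 1,
    max_depth >= 0
  )
  structure(
    list(
      n_trees = as.integer(n_trees),
      subsample_fraction = subsample_fraction,
      structure_fraction = structure_fraction,
      min_leaf_treated = as.integer(min_leaf_treated),
      min_leaf_control = as.integer(min_leaf_control),
      max_depth = as.integer(max_depth),
      honest = isTRUE(honest),
      subsample_is_structure = isTRUE(subsample_is_structure),
      seed = as.integer(seed)
    ),
    class = "forest_params"
  )
}

# Internal matrix representation of a discretized training table: ordinal
# bins 1..B per covariate (binary coded 1/2), excluded covariates dropped.
forest_data <- function(table, cutpoints) {
  covs <- covariate_columns(table)
  usable <- covs[vapply(covs, function(cv) {
    entry <- cutpoints[[cv]]
    is.null(entry) || !isTRUE(entry$excluded)
  }, logical(1))]
  X <- matrix(0L, nrow(table), length(usable),
              dimnames = list(NULL, usable))
  n_bins <- integer(length(usable))
  binary <- vapply(usable, function(cv) {
    entry <- cutpoints[[cv]]
    if (!is.null(entry)) entry$kind == "binary" else is_binary_col(table[[cv]])
  }, logical(1))
  for (j in seq_along(usable)) {
    cv <- usable[j]
    entry <- cutpoints[[cv]]
    if (binary[j]) {
      X[, j] <- as.integer(table[[cv]]) + 1L
      n_bins[j] <- 2L
    } else {
      X[, j] <- as.integer(table[[cv]])
      n_bins[j] <- if (!is.null(entry)) entry$n_bins else max(X[, j])
    }
  }
  list(
    X = X, n_bins = n_bins, covariates = usable,
    arm = as.integer(table$arm), event = as.integer(table$event_indicator),
    id = table$id,
    binary = binary
  )
}

#' Score a single candidate split
#'
#' Computes the honest causal-tree objective for one (covariate, threshold)
#' candidate on a node's structure-half data: the sum over the two children
#' of `n_child * tau_child^2`, where `tau_child` is the child's
#' treated-minus-control event-rate difference. Higher is better. Returns
#' `-Inf` when either child has an empty arm (inadmissible candidate).
#'
#' @param x_bin Integer bin values of the candidate covariate at the node.
#' @param arm 0/1 treatment assignment.
#' @param event 0/1 event indicator.
#' @param k Threshold: left child is `bin <= k`.
#' @return The score (a real; `-Inf` for an inadmissible candidate).
#' @export
split_criterion <- function(x_bin, arm, event, k) {
  left <- x_bin <= k
  score <- 0
  for (side in list(left, !left)) {
    n1 <- sum(side & arm == 1L)
    n0 <- sum(side & arm == 0L)
    if (n1 == 0L || n0 == 0L) {
      return(-Inf)
    }
    tau <- sum(event[side & arm == 1L]) / n1 -
      sum(event[side & arm == 0L]) / n0
    score <- score + (n1 + n0) * tau^2
  }
  score
}

# Vectorized search over every (covariate, threshold) candidate at a node.
# Counts per (bin, arm) cell are tabulated once per covariate; cumulative
# sums then give every threshold's child counts in O(B). Admissibility
# requires both children to meet per-arm minima in the structure AND the
# estimation half. Ties: first covariate in schema order, lowest threshold.
best_split <- function(fd, idx_str, idx_est, params) {
  b_str <- fd$X[idx_str, , drop = FALSE]
  arm_str <- fd$arm[idx_str]
  ev_str <- fd$event[idx_str]
  b_est <- fd$X[idx_est, , drop = FALSE]
  arm_est <- fd$arm[idx_est]
  mt <- params$min_leaf_treated
  mc <- params$min_leaf_control
  best <- list(score = -Inf, cov = NA_integer_, k = NA_integer_)
  for (j in seq_along(fd$covariates)) {
    B <- fd$n_bins[j]
    if (B < 2L) next
    bj <- b_str[, j]
    cell <- bj + B * arm_str
    cnt <- tabulate(cell, 2L * B)
    evt <- tabulate(cell[ev_str == 1L], 2L * B)
    n0 <- cnt[1:B]; n1 <- cnt[(B + 1L):(2L * B)]
    e0 <- evt[1:B]; e1 <- evt[(B + 1L):(2L * B)]
    cellE <- b_est[, j] + B * arm_est
    cntE <- tabulate(cellE, 2L * B)
    n0E <- cntE[1:B]; n1E <- cntE[(B + 1L):(2L * B)]

    ks <- seq_len(B - 1L)
    nL0 <- cumsum(n0)[ks]; nL1 <- cumsum(n1)[ks]
    eL0 <- cumsum(e0)[ks]; eL1 <- cumsum(e1)[ks]
    nR0 <- sum(n0) - nL0; nR1 <- sum(n1) - nL1
    eR0 <- sum(e0) - eL0; eR1 <- sum(e1) - eL1
    nL0E <- cumsum(n0E)[ks]; nL1E <- cumsum(n1E)[ks]
    nR0E <- sum(n0E) - nL0E; nR1E <- sum(n1E) - nL1E

    ok <- nL1 >= mt & nR1 >= mt & nL0 >= mc & nR0 >= mc &
      nL1E >= mt & nR1E >= mt & nL0E >= mc & nR0E >= mc
    if (!any(ok)) next
    tauL <- eL1 / nL1 - eL0 / nL0
    tauR <- eR1 / nR1 - eR0 / nR0
    sc <- (nL0 + nL1) * tauL^2 + (nR0 + nR1) * tauR^2
    sc[!ok] <- -Inf
    kbest <- which.max(sc)
    if (sc[kbest] > best$score) {
      best <- list(score = sc[kbest], cov = j, k = as.integer(kbest))
    }
  }
  best
}

node_tau <- function(fd, idx) {
  a <- fd$arm[idx]
  e <- fd$event[idx]
  n1 <- sum(a == 1L)
  n0 <- sum(a == 0L)
  if (n1 == 0L || n0 == 0L) {
    return(NA_real_)
  }
  sum(e[a == 1L]) / n1 - sum(e[a == 0L]) / n0
}

#' Grow a single honest causal tree
#'
#' Draws the tree's subsample (without replacement), partitions it into
#' structure and estimation halves, and grows recursively: at each node
#' every (covariate, ordinal threshold) candidate is scored with
#' [split_criterion()]'s objective, the best admissible split is accepted
#' if it strictly improves on the unsplit node's score, and growth stops
#' at `max_depth` or when no admissible improving split exists. Leaf
#' `tau_hat` values are estimated on the estimation half only (honesty).
#'
#' @param fd Internal forest data (from the discretized training table);
#'   users normally call [build_forest()] instead.
#' @param params A [forest_params()].
#' @param tree_seed Integer seed for this tree's subsampling.
#' @return A tree: nested list of nodes; leaves carry `tau_hat`, per-arm
#'   counts in both halves, and the root-to-leaf condition path.
#' @export
grow_tree <- function(fd, params, tree_seed) {
  n <- length(fd$arm)
  with_seed(tree_seed, {
    m <- max(2L, round(params$subsample_fraction * n))
    sub <- sample.int(n, m)
    if (params$subsample_is_structure) {
      idx_str <- sub
      idx_est <- setdiff(seq_len(n), sub)
    } else {
      n_str <- max(1L, round(params$structure_fraction * m))
      idx_str <- sub[seq_len(n_str)]
      idx_est <- sub[-seq_len(n_str)]
    }
    if (!params$honest) {
      idx_est <- idx_str
    }

    root_ok <- sum(fd$arm[idx_str] == 1L) >= params$min_leaf_treated &&
      sum(fd$arm[idx_str] == 0L) >= params$min_leaf_control &&
      sum(fd$arm[idx_est] == 1L) >= params$min_leaf_treated &&
      sum(fd$arm[idx_est] == 0L) >= params$min_leaf_control

    make_leaf <- function(i_str, i_est, path) {
      a_est <- fd$arm[i_est]
      list(
        type = "leaf",
        tau_hat = node_tau(fd, i_est),
        n_structure_treated = sum(fd$arm[i_str] == 1L),
        n_structure_control = sum(fd$arm[i_str] == 0L),
        n_estimation_treated = sum(a_est == 1L),
        n_estimation_control = sum(a_est == 0L),
        structure_ids = fd$id[i_str],
        estimation_ids = fd$id[i_est],
        path = path
      )
    }

    grow <- function(i_str, i_est, depth, path) {
      if (depth >= params$max_depth) {
        return(make_leaf(i_str, i_est, path))
      }
      bs <- best_split(fd, i_str, i_est, params)
      if (!is.finite(bs$score)) {
        return(make_leaf(i_str, i_est, path))
      }
      tau0 <- node_tau(fd, i_str)
      node_score <- if (is.na(tau0)) -Inf else length(i_str) * tau0^2
      if (bs$score <= node_score + 1e-12) {
        return(make_leaf(i_str, i_est, path))
      }
      j <- bs$cov
      k <- bs$k
      go_left_str <- fd$X[i_str, j] <= k
      go_left_est <- fd$X[i_est, j] <= k
      cond_l <- list(covariate = fd$covariates[j], op = "le", k = k,
                     binary = fd$binary[j])
      cond_r <- list(covariate = fd$covariates[j], op = "gt", k = k,
                     binary = fd$binary[j])
      list(
        type = "split",
        covariate = fd$covariates[j],
        k = k,
        left = grow(i_str[go_left_str], i_est[go_left_est], depth + 1L,
                    c(path, list(cond_l))),
        right = grow(i_str[!go_left_str], i_est[!go_left_est], depth + 1L,
                     c(path, list(cond_r)))
      )
    }

    if (!root_ok) {
      warning("tree root violates per-arm minima; returning a single leaf",
              call. = FALSE)
      make_leaf(idx_str, idx_est, list())
    } else {
      grow(idx_str, idx_est, 0L, list())
    }
  })
}

tree_leaves <- function(node) {
  if (node$type == "leaf") {
    return(list(node))
  }
  c(tree_leaves(node$left), tree_leaves(node$right))
}

#' Build an honest causal forest
#'
#' Grows `n_trees` independent honest causal trees ([grow_tree()]) with
#' per-tree seeds derived from the master seed, so the forest is a
#' deterministic function of (data, params) regardless of execution order.
#'
#' @param table A discretized training table (see
#'   [discretize_covariates()]) with `arm` and `event_indicator` columns.
#' @param params A [forest_params()].
#' @param cutpoints The cutpoint map used to discretize `table`.
#' @return An object of class `harm_forest`: `trees`, flattened `leaves`,
#'   `n_leaves`, `params`, `covariates`, `cutpoints`.
#' @export
build_forest <- function(table, params = forest_params(), cutpoints = NULL) {
  fd <- forest_data(table, cutpoints %||% list())
  trees <- lapply(seq_len(params$n_trees), function(t) {
    grow_tree(fd, params, derive_seed(params$seed, paste0("tree", t)))
  })
  leaves <- list()
  for (t in seq_along(trees)) {
    lv <- tree_leaves(trees[[t]])
    for (l in seq_along(lv)) {
      lv[[l]]$tree <- t
      lv[[l]]$leaf <- l
    }
    leaves <- c(leaves, lv)
  }
  structure(
    list(
      trees = trees,
      leaves = leaves,
      n_leaves = length(leaves),
      params = params,
      covariates = fd$covariates,
      cutpoints = cutpoints
    ),
    class = "harm_forest"
  )
}

#' @export
print.harm_forest <- function(x, ...) {
  taus <- vapply(x$leaves, function(l) l$tau_hat %||% NA_real_, numeric(1))
  cat("Honest causal forest:", length(x$trees), "trees,",
      x$n_leaves, "leaves\n")
  cat(sprintf("  harm leaves (tau_hat > 0): %d (%.1f%%)\n",
              sum(taus > 0, na.rm = TRUE),
              100 * mean(taus > 0, na.rm = TRUE)))
  invisible(x)
}
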