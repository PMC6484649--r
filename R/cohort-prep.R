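# Covariate discretization and entropy-balanced 50/50 split selection.

is_binary_col <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2L && all(u %in% c(0, 1))
}

#' Discretize continuous covariates into quantile bins
#'
#' Replaces each continuous baseline covariate by an ordinal bin index
#' 1..`n_bins` computed from empirical quantiles (linear interpolation,
#' half-open bins `(a, b]`: values equal to a cutpoint fall in the lower
#' bin). Binary covariates pass through unchanged. Supplying a previously
#' derived `cutpoint_map` applies those frozen cuts instead — the mechanism
#' for carrying training-set bin boundaries onto test data.
#'
#' A constant covariate collapses to a single bin with a warning and is
#' flagged `excluded` in the returned map so splitters can skip it.
#'
#' @param table A trial table (see [generate_cohort()]); covariates are all
#'   columns other than `id`, `site_id`, `arm`, `event_time`,
#'   `event_indicator`.
#' @param n_bins Number of quantile bins for continuous covariates
#'   (default 4, i.e. quartiles; 3 gives terciles).
#' @param cutpoints Optional cutpoint map from a previous call.
#' @return A list with `table` (discretized) and `cutpoints` (the map
#'   used: per covariate `kind`, `cuts`, `n_bins`, `excluded`).
#' @export
discretize_covariates <- function(table, n_bins = 4L, cutpoints = NULL) {
  if (is.null(cutpoints) && n_bins < 2L) {
    stop("n_bins must be >= 2", call. = FALSE)
  }
  covs <- covariate_columns(table)
  if (!is.null(cutpoints)) {
    unknown <- setdiff(names(cutpoints), covs)
    if (length(unknown)) {
      stop("cutpoint map names unknown covariate(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  map <- list()
  out <- table
  for (cv in covs) {
    x <- table[[cv]]
    if (!is.null(cutpoints)) {
      entry <- cutpoints[[cv]]
      if (is.null(entry)) {
        stop("cutpoint map has no entry for covariate '", cv, "'",
             call. = FALSE)
      }
    } else if (is_binary_col(x)) {
      entry <- list(kind = "binary", cuts = numeric(), n_bins = 2L,
                    excluded = FALSE)
    } else {
      cuts <- unname(quantile(x, probs = seq_len(n_bins - 1L) / n_bins,
                              type = 7, names = FALSE))
      cuts <- unique(cuts)
      excluded <- FALSE
      if (length(cuts) == 0L || length(unique(x)) == 1L) {
        warning("covariate '", cv, "' is constant; collapsed to one bin ",
                "and excluded from splitting", call. = FALSE)
        cuts <- numeric()
        excluded <- TRUE
      }
      entry <- list(kind = "continuous", cuts = cuts,
                    n_bins = length(cuts) + 1L, excluded = excluded)
    }
    map[[cv]] <- entry
    if (entry$kind == "continuous") {
      out[[cv]] <- findInterval(x, entry$cuts, left.open = TRUE) + 1L
    } else {
      out[[cv]] <- as.integer(x)
    }
  }
  list(table = out, cutpoints = map)
}

# Entropy-balancing dual: given a moment matrix X (rows = units) and a
# target mean vector m, find unit weights w_i > 0, sum 1, with X'w = m and
# minimal KL(w || uniform). Solved via the unconstrained smooth convex dual
# g(lambda) = log sum_i exp(-z_i'lambda) on centred/scaled moments z; at the
# optimum KL = log(n) - g(lambda*). Returns +Inf when the target mean lies
# outside the convex hull of the rows (dual unbounded).
eb_solve <- function(X, target, tol = 1e-9, max_score = 30) {
  X <- as.matrix(X)
  n <- nrow(X)
  scl <- apply(X, 2, sd)
  keep <- scl > 0
  if (any(!keep)) {
    # A moment constant in the sample is satisfiable iff it equals the
    # target; otherwise balance is infeasible.
    if (any(abs(X[1, !keep] - target[!keep]) > 1e-10)) {
      return(list(score = Inf, weights = NULL, converged = FALSE))
    }
    X <- X[, keep, drop = FALSE]
    target <- target[keep]
    scl <- scl[keep]
  }
  if (ncol(X) == 0L) {
    return(list(score = 0, weights = rep(1 / n, n), converged = TRUE))
  }
  Z <- sweep(sweep(X, 2, target), 2, scl, "/")
  fn <- function(l) {
    u <- -drop(Z %*% l)
    mx <- max(u)
    mx + log(sum(exp(u - mx)))
  }
  gr <- function(l) {
    u <- -drop(Z %*% l)
    u <- u - max(u)
    w <- exp(u)
    w <- w / sum(w)
    -drop(crossprod(Z, w))
  }
  opt <- optim(rep(0, ncol(Z)), fn, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  score <- log(n) - opt$value
  g <- gr(opt$par)
  converged <- max(abs(g)) < 1e-5
  if (!converged || score > max_score) {
    return(list(score = Inf, weights = NULL, converged = FALSE))
  }
  u <- -drop(Z %*% opt$par)
  u <- u - max(u)
  w <- exp(u)
  w <- w / sum(w)
  list(score = max(score, 0), weights = w, converged = TRUE)
}

balance_moment_matrix <- function(table) {
  covs <- covariate_columns(table)
  as.matrix(table[, c(covs, "event_indicator", "arm")])
}

#' Entropy-balance score of a candidate train/test split
#'
#' Fits entropy-balancing weights on the train half so that its weighted
#' first moments of every baseline covariate, the event indicator and the
#' arm indicator match the full-sample means, and returns the
#' Kullback-Leibler divergence of the fitted weights from uniform. A score
#' of 0 means uniform weights already balance the half perfectly; `Inf`
#' flags an infeasible candidate (a full-sample mean outside the train
#' half's convex hull).
#'
#' @param split A split assignment (list with integer `train_ids`), or a
#'   logical/character vector over rows of `table` marking the train half.
#' @param table The full trial table the split partitions.
#' @return Nonnegative score (KL divergence, nats), `Inf` if infeasible.
#' @export
entropy_balance_score <- function(split, table) {
  train <- if (is.list(split)) {
    table$id %in% split$train_ids
  } else if (is.character(split)) {
    split == "train"
  } else {
    as.logical(split)
  }
  M <- balance_moment_matrix(table)
  eb_solve(M[train, , drop = FALSE], colMeans(M))$score
}

#' Propose and score random 50/50 splits
#'
#' Draws `n_candidates` random half splits of the cohort (train/test sizes
#' differing by at most one) and scores each by [entropy_balance_score()].
#' Also records, per candidate, the standardized mean difference of every
#' balanced moment between the train half and the full sample.
#'
#' @param table Trial table.
#' @param n_candidates Number of candidate splits (default 1000).
#' @param seed Integer seed; candidates are deterministic given it.
#' @return A list of candidate splits, each a list with `candidate`,
#'   `train_ids`, `test_ids`, `score`, `smd` (named vector), `seed`.
#' @export
propose_and_score_splits <- function(table, n_candidates = 1000L, seed = 1L) {
  n <- nrow(table)
  if (n < 20L) {
    stop("cohort too small to split meaningfully (n < 20)", call. = FALSE)
  }
  if (n_candidates < 1L) {
    stop("n_candidates must be >= 1", call. = FALSE)
  }
  M <- balance_moment_matrix(table)
  full_mean <- colMeans(M)
  full_sd <- apply(M, 2, sd)
  full_sd[full_sd == 0] <- 1
  n_train <- n %/% 2L
  with_seed(derive_seed(seed, "splits"), {
    lapply(seq_len(n_candidates), function(k) {
      train_idx <- sample.int(n, n_train)
      sol <- eb_solve(M[train_idx, , drop = FALSE], full_mean)
      smd <- (colMeans(M[train_idx, , drop = FALSE]) - full_mean) / full_sd
      list(
        candidate = k,
        train_ids = sort(table$id[train_idx]),
        test_ids = sort(table$id[-train_idx]),
        score = sol$score,
        smd = smd,
        seed = seed
      )
    })
  })
}

#' Select the best-balanced split
#'
#' Returns the candidate with the minimal entropy-balance score; ties are
#' broken by lowest candidate index, and infeasible (`Inf`) candidates are
#' never selected.
#'
#' @param candidates Output of [propose_and_score_splits()].
#' @return The selected candidate split (with `selected = TRUE` added).
#' @export
select_split <- function(candidates) {
  scores <- vapply(candidates, `[[`, numeric(1), "score")
  if (all(!is.finite(scores))) {
    stop("no feasible split candidate; consider a larger cohort or fewer ",
         "balanced moments", call. = FALSE)
  }
  best <- which.min(scores) # first minimum = lowest candidate index
  out <- candidates[[best]]
  out$selected <- TRUE
  out
}
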