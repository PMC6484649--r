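# Harvest harm-indicating leaves from the forest and distill them into a
# ranked, deduplicated set of testable subgroup hypotheses.

#' Harvest harm leaves
#'
#' Returns exactly the forest leaves whose honest association estimate is
#' strictly positive (`tau_hat > 0`), i.e. subgroups whose event rate is
#' estimated higher under treatment. Ties at exactly zero count as
#' benefit/neutral and are not returned.
#'
#' @param forest A [build_forest()] result.
#' @return A list with `leaves` (the harm leaves, with their root-to-leaf
#'   condition paths), `n_total` (all leaves), and `harm_fraction`.
#' @export
harvest_harm_leaves <- function(forest) {
  taus <- vapply(forest$leaves, function(l) {
    if (is.null(l$tau_hat) || is.na(l$tau_hat)) -Inf else l$tau_hat
  }, numeric(1))
  harm <- forest$leaves[taus > 0]
  list(
    leaves = harm,
    n_total = forest$n_leaves,
    harm_fraction = if (forest$n_leaves > 0) {
      length(harm) / forest$n_leaves
    } else {
      NA_real_
    }
  )
}

#' Covariate frequency among harm leaves
#'
#' Counts, for each covariate, the number and fraction of harm leaves
#' whose root-to-leaf path uses it (each covariate counted at most once
#' per leaf), sorted descending.
#'
#' @param harm Output of [harvest_harm_leaves()] (or a plain list of
#'   leaves).
#' @return A `data.frame` with columns `covariate`, `n_leaves`, `fraction`.
#' @export
covariate_frequency <- function(harm) {
  leaves <- if (is.list(harm) && !is.null(harm$leaves)) harm$leaves else harm
  if (length(leaves) == 0L) {
    return(data.frame(covariate = character(), n_leaves = integer(),
                      fraction = numeric()))
  }
  per_leaf <- lapply(leaves, function(l) {
    unique(vapply(l$path, `[[`, "", "covariate"))
  })
  tab <- sort(table(unlist(per_leaf)), decreasing = TRUE)
  data.frame(
    covariate = names(tab),
    n_leaves = as.integer(tab),
    fraction = as.numeric(tab) / length(leaves),
    row.names = NULL
  )
}

# Canonicalize a leaf path into per-covariate bin intervals (lo, hi]:
# "le k" tightens hi, "gt k" tightens lo. Returns NULL for a contradictory
# conjunction (lo >= hi).
canonicalize_path <- function(path, cutpoints) {
  covs <- unique(vapply(path, `[[`, "", "covariate"))
  out <- list()
  for (cv in covs) {
    entry <- cutpoints[[cv]]
    B <- if (!is.null(entry)) {
      if (entry$kind == "binary") 2L else entry$n_bins
    } else {
      max(vapply(path, function(c) if (c$covariate == cv) c$k else 0L,
                 integer(1))) + 1L
    }
    lo <- 0L
    hi <- B
    binary <- FALSE
    for (cond in path) {
      if (cond$covariate != cv) next
      binary <- isTRUE(cond$binary)
      if (cond$op == "le") {
        hi <- min(hi, cond$k)
      } else {
        lo <- max(lo, cond$k)
      }
    }
    if (lo >= hi) {
      return(NULL)
    }
    out[[cv]] <- list(covariate = cv, lo = lo, hi = hi, n_bins = B,
                      binary = binary)
  }
  out
}

# Render a canonical bin interval as thresholds in original units.
render_condition <- function(cond, cutpoints) {
  entry <- cutpoints[[cond$covariate]]
  if (cond$binary || (!is.null(entry) && entry$kind == "binary")) {
    val <- if (cond$lo >= 1L) 1L else 0L
    return(list(covariate = cond$covariate, type = "equals", value = val,
                label = sprintf("%s = %d", cond$covariate, val)))
  }
  cuts <- if (!is.null(entry)) entry$cuts else numeric()
  lower <- if (cond$lo > 0L && cond$lo <= length(cuts)) cuts[cond$lo] else NA_real_
  upper <- if (cond$hi < cond$n_bins && cond$hi <= length(cuts)) {
    cuts[cond$hi]
  } else {
    NA_real_
  }
  label <- if (!is.na(lower) && !is.na(upper)) {
    sprintf("%.6g < %s <= %.6g", lower, cond$covariate, upper)
  } else if (!is.na(lower)) {
    sprintf("%s > %.6g", cond$covariate, lower)
  } else if (!is.na(upper)) {
    sprintf("%s <= %.6g", cond$covariate, upper)
  } else {
    sprintf("%s: any", cond$covariate)
  }
  list(covariate = cond$covariate, type = "interval",
       lower = lower, upper = upper,
       lo_bin = cond$lo, hi_bin = cond$hi, label = label)
}

condition_key <- function(canon) {
  covs <- sort(names(canon))
  paste(vapply(covs, function(cv) {
    c0 <- canon[[cv]]
    sprintf("%s:(%d,%d]", cv, c0$lo, c0$hi)
  }, ""), collapse = " & ")
}

#' Subgroup membership under a hypothesis
#'
#' Evaluates a distilled hypothesis's frozen original-unit thresholds on a
#' raw (undiscretized) trial table. Interval conditions are half-open
#' (`lower < x <= upper`), matching the half-open quantile bins.
#'
#' @param hypothesis A single hypothesis from [distill_hypotheses()].
#' @param table A raw trial table.
#' @return Logical vector of membership.
#' @export
subgroup_membership <- function(hypothesis, table) {
  member <- rep(TRUE, nrow(table))
  for (cond in hypothesis$conditions) {
    x <- table[[cond$covariate]]
    if (is.null(x)) {
      stop("table lacks covariate '", cond$covariate, "'", call. = FALSE)
    }
    if (cond$type == "equals") {
      member <- member & (x == cond$value)
    } else {
      if (!is.na(cond$lower)) member <- member & (x > cond$lower)
      if (!is.na(cond$upper)) member <- member & (x <= cond$upper)
    }
  }
  member
}

#' Distill harm leaves into ranked subgroup hypotheses
#'
#' Canonicalizes each harm leaf's path (merging conditions on the same
#' covariate into the tightest bin interval; contradictory conjunctions
#' are dropped), optionally truncates each conjunction to the
#' `max_conditions` covariates most frequent across harm leaves,
#' deduplicates identical canonical conjunctions (summing leaf support),
#' translates bin thresholds into original units via the training
#' cutpoint map — these unit thresholds are then FROZEN, so test-set
#' membership uses them, not re-derived quantiles — and returns the top
#' `top_k` hypotheses ranked by number of contributing leaves (ties by
#' mean `tau_hat`), or by mean `tau_hat` if `rank_by = "tau"`.
#'
#' @param harm Output of [harvest_harm_leaves()].
#' @param cutpoints Training cutpoint map.
#' @param training_table Raw training table used to compute support counts.
#' @param max_conditions Maximum covariates per conjunction (default 3).
#' @param top_k Number of hypotheses returned (default 5).
#' @param rank_by `"support"` (default) or `"tau"`.
#' @return A list of hypotheses; each has `conditions` (unit thresholds),
#'   `bin_conditions`, `label`, `n_leaves`, `mean_tau_hat`, `support`,
#'   `rank`.
#' @export
distill_hypotheses <- function(harm, cutpoints, training_table,
                               max_conditions = 3L, top_k = 5L,
                               rank_by = c("support", "tau")) {
  rank_by <- match.arg(rank_by)
  leaves <- if (!is.null(harm$leaves)) harm$leaves else harm
  if (length(leaves) == 0L) {
    return(list())
  }
  freq <- covariate_frequency(leaves)
  keep_order <- freq$covariate

  agg <- new.env(parent = emptyenv())
  n_dropped <- 0L
  for (l in leaves) {
    canon <- canonicalize_path(l$path, cutpoints)
    if (is.null(canon)) {
      n_dropped <- n_dropped + 1L
      next
    }
    if (length(canon) == 0L) {
      next # unsplit root leaf: defines no subgroup
    }
    if (length(canon) > max_conditions) {
      ord <- order(match(names(canon), keep_order))
      canon <- canon[ord[seq_len(max_conditions)]]
    }
    key <- condition_key(canon)
    cur <- if (!is.null(agg[[key]])) {
      agg[[key]]
    } else {
      list(canon = canon, n_leaves = 0L, tau_sum = 0)
    }
    cur$n_leaves <- cur$n_leaves + 1L
    cur$tau_sum <- cur$tau_sum + l$tau_hat
    agg[[key]] <- cur
  }
  if (n_dropped > 0L) {
    message(n_dropped, " harm leaf/leaves dropped: contradictory merged ",
            "conditions")
  }
  keys <- ls(agg)
  if (length(keys) == 0L) {
    return(list())
  }
  hyps <- lapply(keys, function(key) {
    cur <- agg[[key]]
    conds <- lapply(cur$canon, render_condition, cutpoints = cutpoints)
    hyp <- list(
      conditions = unname(conds),
      bin_conditions = unname(cur$canon),
      label = paste(vapply(conds, `[[`, "", "label"), collapse = " & "),
      n_leaves = cur$n_leaves,
      mean_tau_hat = cur$tau_sum / cur$n_leaves,
      key = key
    )
    hyp$support <- sum(subgroup_membership(hyp, training_table))
    hyp
  })
  hyps <- Filter(function(h) h$support > 0, hyps)
  if (length(hyps) == 0L) {
    return(list())
  }
  nl <- vapply(hyps, `[[`, integer(1), "n_leaves")
  mt <- vapply(hyps, `[[`, numeric(1), "mean_tau_hat")
  ord <- if (rank_by == "support") {
    order(-nl, -mt, vapply(hyps, `[[`, "", "key"))
  } else {
    order(-mt, -nl, vapply(hyps, `[[`, "", "key"))
  }
  hyps <- hyps[ord[seq_len(min(top_k, length(hyps)))]]
  for (i in seq_along(hyps)) {
    hyps[[i]]$rank <- i
  }
  hyps
}
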