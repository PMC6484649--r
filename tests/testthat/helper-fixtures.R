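# Fixtures and independent oracles used across the suite.

# A trial table realizing exact per-cell (membership x arm) participant and
# event counts, for worked-example arithmetic on published count layouts.
# cells: list of lists with fields member (0/1), arm (0/1), n, events.
counts_table <- function(cells) {
  rows <- lapply(cells, function(cl) {
    data.frame(
      member = rep(cl$member, cl$n),
      arm = rep(cl$arm, cl$n),
      event_indicator = rep(c(1L, 0L), c(cl$events, cl$n - cl$events))
    )
  })
  df <- do.call(rbind, rows)
  n <- nrow(df)
  data.frame(
    id = seq_len(n),
    site_id = rep(1L, n),
    arm = df$arm,
    marker = df$member, # membership encoded as a baseline covariate
    event_time = rep(1, n),
    event_indicator = df$event_indicator
  )
}

# Small default simulated cohort reused by several tests.
small_cohort <- function(seed = 42, n = 800, extra = 0,
                         covariates = default_covariate_spec()[1:6]) {
  cfg <- sim_config(
    n_participants = n, n_sites = 8, covariate_spec = covariates,
    harm_subgroup_rule = if (extra != 0) smoker_high_sbp_rule() else list(),
    subgroup_extra_log_hazard_ratio = extra, seed = seed
  )
  list(config = cfg, cohort = generate_cohort(cfg))
}

# Independent Breslow partial log-likelihood for a single binary covariate,
# optionally stratified; used as the brute-force oracle for fit_cox.
breslow_loglik <- function(beta, time, event, x, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, length(time))
  ll <- 0
  for (s in unique(strata)) {
    sel <- strata == s
    t_s <- time[sel]; e_s <- event[sel]; x_s <- x[sel]
    for (i in which(e_s == 1L)) {
      risk <- t_s >= t_s[i]
      ll <- ll + beta * x_s[i] - log(sum(exp(beta * x_s[risk])))
    }
  }
  ll
}

# Grid maximization of the enumerated partial likelihood (coarse grid then
# a refinement pass), accurate to ~1e-4.
grid_beta <- function(time, event, x, strata = NULL) {
  grid <- seq(-6, 6, by = 0.01)
  ll <- vapply(grid, breslow_loglik, numeric(1),
               time = time, event = event, x = x, strata = strata)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  llf <- vapply(fine, breslow_loglik, numeric(1),
                time = time, event = event, x = x, strata = strata)
  fine[which.max(llf)]
}

# Brute-force solution of the 1-moment entropy-balancing dual on a grid:
# weights w_i proportional to exp(-lambda * x_i) with weighted mean equal
# to the target; returns KL(w || uniform).
eb_kl_1d_grid <- function(x, target) {
  n <- length(x)
  kl_at <- function(lambda) {
    w <- exp(-lambda * x)
    w <- w / sum(w)
    list(mean = sum(w * x), kl = sum(w * log(n * w)))
  }
  grid <- seq(-60, 60, length.out = 240001)
  means <- vapply(grid, function(l) kl_at(l)$mean, numeric(1))
  best <- grid[which.min(abs(means - target))]
  fine <- seq(best - 0.001, best + 0.001, length.out = 20001)
  means_f <- vapply(fine, function(l) kl_at(l)$mean, numeric(1))
  kl_at(fine[which.min(abs(means_f - target))])$kl
}

# Exhaustive split search matching the documented tie rule (first
# covariate in schema order, lowest threshold), used as the oracle for the
# vectorized best_split inside grow_tree.
exhaustive_best_split <- function(X, arm, event, idx_str, idx_est, n_bins,
                                  min_t, min_c) {
  best <- list(score = -Inf, cov = NA, k = NA)
  for (j in seq_len(ncol(X))) {
    for (k in seq_len(n_bins[j] - 1L)) {
      admissible <- TRUE
      for (half in list(idx_str, idx_est)) {
        left <- X[half, j] <= k
        for (side in list(left, !left)) {
          if (sum(arm[half][side] == 1L) < min_t ||
              sum(arm[half][side] == 0L) < min_c) {
            admissible <- FALSE
          }
        }
      }
      if (!admissible) next
      sc <- split_criterion(X[idx_str, j], arm[idx_str], event[idx_str], k)
      if (is.finite(sc) && sc > best$score + 1e-12) {
        best <- list(score = sc, cov = j, k = k)
      }
    }
  }
  best
}
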