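leaf <- function(tau, path = list()) {
  list(type = "leaf", tau_hat = tau, path = path,
       n_structure_treated = 5L, n_structure_control = 5L,
       n_estimation_treated = 5L, n_estimation_control = 5L,
       structure_ids = integer(), estimation_ids = integer(),
       tree = 1L, leaf = 1L)
}
cond <- function(cv, op, k, binary = FALSE) {
  list(covariate = cv, op = op, k = k, binary = binary)
}
fake_forest <- function(leaves) {
  structure(list(trees = list(), leaves = leaves,
                 n_leaves = length(leaves),
                 params = forest_params(n_trees = 1),
                 covariates = character(), cutpoints = list()),
            class = "harm_forest")
}

test_that("harvest keeps strictly positive tau leaves only", {
  fo <- fake_forest(list(leaf(-0.1), leaf(0), leaf(0.2)))
  h <- harvest_harm_leaves(fo)
  expect_length(h$leaves, 1L)
  expect_equal(h$leaves[[1]]$tau_hat, 0.2)
  expect_equal(h$harm_fraction, 1 / 3)

  # a single depth-0 tree at exactly zero yields nothing
  h0 <- harvest_harm_leaves(fake_forest(list(leaf(0))))
  expect_length(h0$leaves, 0L)
  expect_equal(h0$harm_fraction, 0)
})

test_that("covariate frequency counts each covariate once per leaf", {
  l1 <- leaf(0.1, list(cond("A", "le", 1), cond("B", "gt", 1),
                       cond("A", "gt", 0)))
  l2 <- leaf(0.2, list(cond("A", "le", 2)))
  tab <- covariate_frequency(list(l1, l2))
  expect_equal(tab$covariate, c("A", "B"))
  expect_equal(tab$n_leaves, c(2L, 1L))
  expect_equal(tab$fraction, c(1, 0.5))
  expect_equal(nrow(covariate_frequency(list())), 0L)
})

test_that("distillation merges duplicates and renders unit thresholds", {
  cuts <- list(sbp = list(kind = "continuous", cuts = c(132, 144),
                          n_bins = 3L, excluded = FALSE),
               smoker = list(kind = "binary", cuts = numeric(),
                             n_bins = 2L, excluded = FALSE))
  train <- data.frame(id = 1:40, site_id = 1L, arm = rep_len(c(0L, 1L), 40),
                      sbp = seq(120, 159, 1),
                      smoker = rep_len(c(0L, 1L), 40),
                      event_time = 1, event_indicator = 0L)
  # two leaves with the same canonical path: (sbp bin > 2) and a redundant
  # tightened version of it
  l1 <- leaf(0.3, list(cond("sbp", "gt", 2)))
  l2 <- leaf(0.1, list(cond("sbp", "gt", 1), cond("sbp", "gt", 2)))
  hyps <- distill_hypotheses(list(l1, l2), cuts, train)
  expect_length(hyps, 1L)
  expect_equal(hyps[[1]]$n_leaves, 2L)
  expect_equal(hyps[[1]]$mean_tau_hat, 0.2)
  expect_equal(hyps[[1]]$label, "sbp > 144")
  # frozen unit threshold drives membership: sbp strictly above 144
  expect_equal(sum(subgroup_membership(hyps[[1]], train)),
               sum(train$sbp > 144))
})

test_that("contradictory merged conditions drop the leaf", {
  cuts <- list(x = list(kind = "continuous", cuts = c(1.5, 2.5),
                        n_bins = 3L, excluded = FALSE))
  train <- data.frame(id = 1:20, site_id = 1L, arm = rep_len(c(0L, 1L), 20),
                      x = rep(1:4, 5), event_time = 1, event_indicator = 0L)
  bad <- leaf(0.2, list(cond("x", "le", 1), cond("x", "gt", 2)))
  expect_message(hyps <- distill_hypotheses(list(bad), cuts, train),
                 "contradictory")
  expect_length(hyps, 0L)
})

test_that("binary conditions render as equalities", {
  cuts <- list(smoker = list(kind = "binary", cuts = numeric(),
                             n_bins = 2L, excluded = FALSE))
  train <- data.frame(id = 1:10, site_id = 1L, arm = rep_len(c(0L, 1L), 10),
                      smoker = rep_len(c(0L, 1L), 10),
                      event_time = 1, event_indicator = 0L)
  # internal bins for binary covariates are 1/2; "gt 1" means value 1
  h1 <- distill_hypotheses(list(leaf(0.1, list(cond("smoker", "gt", 1,
                                                    binary = TRUE)))),
                           cuts, train)
  expect_equal(h1[[1]]$label, "smoker = 1")
  expect_equal(sum(subgroup_membership(h1[[1]], train)), 5L)
  h0 <- distill_hypotheses(list(leaf(0.1, list(cond("smoker", "le", 1,
                                                    binary = TRUE)))),
                           cuts, train)
  expect_equal(h0[[1]]$label, "smoker = 0")
})

test_that("ranking prefers leaf support, then mean tau", {
  cuts <- list(x = list(kind = "continuous", cuts = c(2.5), n_bins = 2L,
                        excluded = FALSE),
               y = list(kind = "continuous", cuts = c(2.5), n_bins = 2L,
                        excluded = FALSE))
  train <- data.frame(id = 1:40, site_id = 1L, arm = rep_len(c(0L, 1L), 40),
                      x = rep(1:4, 10), y = rep(1:4, each = 10),
                      event_time = 1, event_indicator = 0L)
  leaves <- list(
    leaf(0.1, list(cond("x", "gt", 1))),
    leaf(0.3, list(cond("x", "gt", 1))),
    leaf(0.9, list(cond("y", "le", 1)))
  )
  hyps <- distill_hypotheses(leaves, cuts, train)
  expect_equal(hyps[[1]]$label, "x > 2.5")
  expect_equal(hyps[[1]]$rank, 1L)
  by_tau <- distill_hypotheses(leaves, cuts, train, rank_by = "tau")
  expect_equal(by_tau[[1]]$label, "y <= 2.5")
})

test_that("truncation keeps the most frequent covariates", {
  cuts <- list(a = list(kind = "continuous", cuts = 0.5, n_bins = 2L,
                        excluded = FALSE),
               b = list(kind = "continuous", cuts = 0.5, n_bins = 2L,
                        excluded = FALSE),
               c = list(kind = "continuous", cuts = 0.5, n_bins = 2L,
                        excluded = FALSE))
  set.seed(1)
  train <- data.frame(id = 1:30, site_id = 1L, arm = rep_len(c(0L, 1L), 30),
                      a = runif(30), b = runif(30), c = runif(30),
                      event_time = 1, event_indicator = 0L)
  leaves <- list(
    leaf(0.2, list(cond("a", "gt", 1), cond("b", "gt", 1), cond("c", "le", 1))),
    leaf(0.2, list(cond("a", "gt", 1), cond("b", "le", 1)))
  )
  hyps <- distill_hypotheses(leaves, cuts, train, max_conditions = 2L)
  covs_used <- unique(unlist(lapply(hyps, function(h) {
    vapply(h$conditions, `[[`, "", "covariate")
  })))
  expect_true(all(covs_used %in% c("a", "b")))
})

test_that("harvest + distill are pure functions of the forest", {
  sc <- small_cohort(seed = 23, n = 500, extra = 1)
  d <- discretize_covariates(sc$cohort, n_bins = 3)
  fo <- build_forest(d$table, forest_params(n_trees = 15, seed = 2),
                     d$cutpoints)
  h1 <- distill_hypotheses(harvest_harm_leaves(fo), d$cutpoints, sc$cohort)
  h2 <- distill_hypotheses(harvest_harm_leaves(fo), d$cutpoints, sc$cohort)
  expect_identical(h1, h2)
})

test_that("top hypothesis has a positive training event-rate difference", {
  hits <- vapply(1:6, function(s) {
    cfg <- sim_config(n_participants = 1200, n_sites = 8,
                      covariate_spec = default_covariate_spec()[1:6],
                      harm_subgroup_rule = smoker_high_sbp_rule(),
                      subgroup_extra_log_hazard_ratio = 1.5, seed = 600 + s)
    co <- generate_cohort(cfg)
    d <- discretize_covariates(co, n_bins = 3)
    fo <- build_forest(d$table, forest_params(n_trees = 25, seed = s),
                       d$cutpoints)
    hyps <- distill_hypotheses(harvest_harm_leaves(fo), d$cutpoints, co,
                               top_k = 1)
    if (length(hyps) == 0) return(NA)
    m <- subgroup_membership(hyps[[1]], co)
    mean(co$event_indicator[m & co$arm == 1]) >
      mean(co$event_indicator[m & co$arm == 0])
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.8)
})
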