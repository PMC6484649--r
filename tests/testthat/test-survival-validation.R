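test_that("fit_cox matches the brute-force partial-likelihood oracle", {
  set.seed(7)
  for (case in 1:8) {
    n <- sample(5:8, 1)
    time <- round(runif(n, 1, 10), 3) # distinct with prob ~1; no ties
    while (anyDuplicated(time)) time <- round(runif(n, 1, 10), 3)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1L
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) == 1) x[1] <- 1L - x[1]
    fit <- fit_cox(time, event, x)
    if (!fit$converged) next # monotone likelihood: oracle unbounded too
    beta <- fit$coefficients$beta[1]
    expect_equal(beta, grid_beta(time, event, x), tolerance = 1e-3)
  }
})

test_that("fit_cox recovers the null at scale", {
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 5000
    arm <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.1)
    cens <- runif(n, 2, 6)
    time <- pmin(t_ev, cens)
    event <- as.integer(t_ev <= cens)
    hr <- fit_cox(time, event, arm)$coefficients$hr[1]
    hr >= 0.9 && hr <= 1.11
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("site stratification absorbs site-specific baseline hazards", {
  set.seed(12)
  n <- 3000
  arm <- rbinom(n, 1, 0.5)
  t1 <- rexp(n, 0.2 * exp(0.5 * arm))
  one_site <- data.frame(time = pmin(t1, 4), event = as.integer(t1 <= 4),
                         arm = arm, site = 1L)
  # duplicate into a second site with a 4x baseline hazard
  two <- one_site
  two$time <- two$time / 4
  two$site <- 2L
  both <- rbind(one_site, two)
  b_strat <- fit_cox(both$time, both$event, both$arm,
                     strata = both$site)$coefficients$beta[1]
  b_unstrat <- fit_cox(both$time, both$event, both$arm)$coefficients$beta[1]
  b_single <- fit_cox(one_site$time, one_site$event,
                      one_site$arm)$coefficients$beta[1]
  expect_equal(b_strat, b_single, tolerance = 0.02)
  expect_gt(abs(b_unstrat - b_single), abs(b_strat - b_single))
})

test_that("degenerate inputs are flagged, not silently returned", {
  # all events in the treated arm of a tiny sample: monotone likelihood
  fit <- fit_cox(time = c(1, 2, 3, 4, 5, 6),
                 event = c(1, 1, 1, 0, 0, 0),
                 treatment = c(1, 1, 1, 0, 0, 0))
  expect_false(fit$converged)
  expect_error(fit_cox(1:4, c(0, 0, 0, 0), c(0, 1, 0, 1)), "no events")
  expect_error(fit_cox(c(0, 1, 2), c(1, 1, 0), c(0, 1, 0)), "> 0")
})

test_that("permutation FDR is 0 for an untouchably large observed effect", {
  set.seed(31)
  n <- 400
  arm <- rbinom(n, 1, 0.5)
  member <- rbinom(n, 1, 0.3)
  # event hazard hugely elevated only for treated members
  rate <- 0.05 * exp(3.5 * arm * member)
  t_ev <- rexp(n, rate)
  time <- pmin(t_ev, 4)
  event <- as.integer(t_ev <= 4)
  res <- permutation_fdr(time, event, arm, member, n_permutations = 50,
                         seed = 5)
  expect_equal(res$fdr, 0)
  expect_equal(res$n_exceed, 0L)
  res2 <- permutation_fdr(time, event, arm, member, n_permutations = 50,
                          seed = 5)
  expect_identical(res, res2)
})

test_that("harm verdict applies both criteria literally", {
  mk <- function(term, hr, p) {
    structure(list(coefficients = data.frame(
      term = term, beta = log(hr), hr = hr, se = 0.5,
      ci_lower = hr * 0.5, ci_upper = hr * 2, p = p
    ), n = 100, n_events = 20, n_strata = 1, ties = "breslow",
    converged = TRUE), class = "cox_result")
  }
  int_fit <- mk(c("treatment", "subgroup", "treatment_x_subgroup"),
                c(0.7, 1.0, 3.5), c(0.2, 0.9, 0.02))
  sub_fit <- mk("treatment", 10.6, 0.03)
  v <- harm_verdict(int_fit, sub_fit, fdr = 0.007)
  expect_true(v$criterion1)
  expect_true(v$criterion2)
  expect_true(v$validated)

  # interaction HR below 1 fails regardless of p
  int_low <- mk(c("treatment", "subgroup", "treatment_x_subgroup"),
                c(0.7, 1.0, 0.8), c(0.2, 0.9, 0.001))
  expect_false(harm_verdict(int_low, sub_fit, 0.001)$validated)

  # FDR at/above threshold fails criterion 1 despite small p
  v_fdr <- harm_verdict(int_fit, sub_fit, fdr = 0.06)
  expect_false(v_fdr$criterion1)
  expect_false(v_fdr$validated)

  # non-converged input -> indeterminate
  bad <- int_fit
  bad$converged <- FALSE
  expect_true(is.na(harm_verdict(bad, sub_fit, 0.01)$validated))
})

test_that("frequency report reproduces printed-count percentages", {
  tab <- counts_table(list(
    list(member = 1, arm = 1, n = 110, events = 12),
    list(member = 1, arm = 0, n = 126, events = 6),
    list(member = 0, arm = 1, n = 2244, events = 109),
    list(member = 0, arm = 0, n = 2200, events = 154)
  ))
  fr <- frequency_report(tab, tab$marker == 1)
  get <- function(g, a) fr$percent[fr$group == g & fr$arm == a]
  expect_equal(get("subgroup", "intensive"), 10.9)
  expect_equal(get("subgroup", "standard"), 4.8)
  expect_equal(fr$n[fr$group == "subgroup" & fr$arm == "intensive"], 110)
  # zero events -> 0.0%
  z <- counts_table(list(list(member = 1, arm = 1, n = 5, events = 0),
                         list(member = 1, arm = 0, n = 5, events = 1)))
  fz <- frequency_report(z, z$marker == 1)
  expect_equal(fz$percent[fz$group == "subgroup" & fz$arm == "intensive"], 0)
  # empty subgroup flagged
  fe <- frequency_report(z, rep(FALSE, nrow(z)))
  expect_true(isTRUE(attr(fe, "flagged_empty")))
})

test_that("NNH reduces to the reciprocal crude risk difference", {
  tab <- counts_table(list(
    list(member = 1, arm = 1, n = 100, events = 10),
    list(member = 1, arm = 0, n = 100, events = 5)
  ))
  # all follow-up times equal, no censoring before horizon
  nnh <- number_needed_to_harm(tab, tab$marker == 1, horizon = 1)
  expect_equal(nnh$nnh, 20)
  expect_false(nnh$no_harm_at_horizon)

  flat <- counts_table(list(
    list(member = 1, arm = 1, n = 100, events = 5),
    list(member = 1, arm = 0, n = 100, events = 5)
  ))
  res <- number_needed_to_harm(flat, flat$marker == 1, horizon = 1)
  expect_true(res$no_harm_at_horizon)
  expect_error(
    number_needed_to_harm(
      counts_table(list(list(member = 1, arm = 1, n = 5, events = 0),
                        list(member = 1, arm = 0, n = 5, events = 0))),
      rep(TRUE, 10)),
    "NNH undefined")
})

test_that("adverse-event analysis reports subgroup and remainder fits", {
  tab <- counts_table(list(
    list(member = 1, arm = 1, n = 110, events = 0),
    list(member = 1, arm = 0, n = 126, events = 0),
    list(member = 0, arm = 1, n = 200, events = 0),
    list(member = 0, arm = 0, n = 200, events = 0)
  ))
  tab$event_time <- 2
  member <- tab$marker == 1
  # AKI events: 11/110 treated members, 4/126 control members
  ae <- data.frame(
    id = c(tab$id[member & tab$arm == 1][1:11],
           tab$id[member & tab$arm == 0][1:4]),
    event_type = "AKI",
    time = 1
  )
  res <- adverse_event_cox(tab, ae, member)
  fr <- res$frequencies
  expect_equal(fr$percent[fr$group == "subgroup" & fr$arm == "intensive"],
               10.0)
  expect_equal(fr$percent[fr$group == "subgroup" & fr$arm == "standard"],
               3.2)
  expect_null(res$remainder) # no AKI events outside the subgroup
  expect_s3_class(res$subgroup, "cox_result")
  expect_gt(res$subgroup$coefficients$hr[1], 1)
})

test_that("validate_hypothesis handles degenerate subgroups gracefully", {
  sc <- small_cohort(seed = 77, n = 300)
  v <- validate_hypothesis(sc$cohort, rep(FALSE, 300),
                           n_permutations = 10, seed = 1)
  expect_true(is.na(v$verdict$validated))
})
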