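# Test-set validation of subgroup hypotheses: site-stratified Cox
# interaction models, a permutation-based FDR for the interaction
# coefficient, the two-criterion harm verdict, event-frequency tables and
# number needed to harm.

#' Fit a (site-stratified) Cox proportional-hazards model
#'
#' Fits the partial likelihood with Breslow tie handling (Efron available)
#' for one of two model forms: treatment alone, or treatment + subgroup +
#' their interaction — the standard heterogeneous-treatment-effect testing
#' model. Stratification gives each stratum (clinic site) its own baseline
#' hazard. Inference is Wald: HR, 95% CI and two-tailed p per coefficient.
#'
#' Monotone partial likelihoods (perfect separation, e.g. all events in
#' one arm of a tiny subgroup) are flagged `converged = FALSE` with the
#' diverging coefficient left as fitted, rather than returned silently.
#'
#' @param time Follow-up time (> 0).
#' @param event 0/1 event indicator.
#' @param treatment 0/1 treatment arm.
#' @param subgroup Optional 0/1 (or logical) subgroup membership; when
#'   supplied the model includes subgroup and treatment-by-subgroup terms.
#' @param strata Optional stratum identifier (clinic site).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_result`: `coefficients` (data.frame
#'   with `term`, `beta`, `hr`, `se`, `ci_lower`, `ci_upper`, `p`), `n`,
#'   `n_events`, `n_strata`, `ties`, `converged`.
#' @export
fit_cox <- function(time, event, treatment, subgroup = NULL, strata = NULL,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  if (any(time <= 0)) {
    stop("all follow-up times must be > 0", call. = FALSE)
  }
  if (sum(event) == 0) {
    stop("no events; Cox model undefined", call. = FALSE)
  }
  df <- data.frame(time = time, event = as.integer(event),
                   treatment = as.numeric(treatment))
  rhs <- "treatment"
  if (!is.null(subgroup)) {
    df$subgroup <- as.numeric(subgroup)
    rhs <- "treatment * subgroup"
  }
  n_strata <- 1L
  if (!is.null(strata)) {
    df$site <- factor(strata)
    n_strata <- nlevels(df$site)
    rhs <- paste(rhs, "+ strata(site)")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  term <- names(beta)
  term[term == "treatment:subgroup"] <- "treatment_x_subgroup"
  converged <- !warned && all(is.finite(beta)) && all(abs(beta) < 15)
  z <- beta / se
  coefs <- data.frame(
    term = term,
    beta = unname(beta),
    hr = unname(exp(beta)),
    se = unname(se),
    ci_lower = unname(exp(beta - qnorm(0.975) * se)),
    ci_upper = unname(exp(beta + qnorm(0.975) * se)),
    p = unname(2 * pnorm(-abs(z))),
    row.names = NULL
  )
  structure(
    list(coefficients = coefs, n = nrow(df), n_events = sum(df$event),
         n_strata = n_strata, ties = ties, converged = converged),
    class = "cox_result"
  )
}

cox_term <- function(result, term) {
  i <- match(term, result$coefficients$term)
  if (is.na(i)) {
    stop("no term '", term, "' in Cox result", call. = FALSE)
  }
  as.list(result$coefficients[i, ])
}

#' Permutation-based FDR for the treatment-by-subgroup interaction
#'
#' Randomly permutes the subgroup indicator across participants (arm,
#' outcome and site fixed) `n_permutations` times, refits the full
#' interaction model each time, and reports the proportion of permuted
#' interaction coefficients strictly greater than the observed one. The
#' quantity is the one-sided exceedance proportion used as the FDR in this
#' validation design (formally it is a permutation p-value; the historical
#' name is kept). Permutation fits that fail to converge are recorded with
#' a `-Inf` sentinel, i.e. they never count as exceeding.
#'
#' @inheritParams fit_cox
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed; the permutation stream is deterministic.
#' @return A list: `beta_observed`, `n_permutations`, `n_exceed`, `fdr`,
#'   `n_nonconverged`, `seed`.
#' @export
permutation_fdr <- function(time, event, treatment, subgroup, strata = NULL,
                            n_permutations = 1000L, seed = 1L,
                            ties = "breslow") {
  obs <- fit_cox(time, event, treatment, subgroup, strata, ties = ties)
  if (!obs$converged) {
    stop("observed interaction fit did not converge; FDR undefined",
         call. = FALSE)
  }
  beta_obs <- cox_term(obs, "treatment_x_subgroup")$beta
  sg <- as.numeric(subgroup)
  betas <- with_seed(derive_seed(seed, "permfdr"), {
    vapply(seq_len(n_permutations), function(i) {
      sg_p <- sample(sg)
      fit <- tryCatch(
        fit_cox(time, event, treatment, sg_p, strata, ties = ties),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        -Inf
      } else {
        cox_term(fit, "treatment_x_subgroup")$beta
      }
    }, numeric(1))
  })
  list(
    beta_observed = beta_obs,
    n_permutations = as.integer(n_permutations),
    n_exceed = sum(betas > beta_obs),
    fdr = mean(betas > beta_obs),
    n_nonconverged = sum(!is.finite(betas)),
    seed = as.integer(seed)
  )
}

#' Two-criterion harm verdict
#'
#' A subgroup hypothesis is validated as harmed only if (1) the hazard
#' ratio for the treatment-by-subgroup interaction exceeds 1 and is
#' statistically significant (two-tailed p < alpha AND permutation FDR <
#' fdr_threshold), and (2) the within-subgroup treatment hazard ratio
#' exceeds 1 and is statistically significant (two-tailed p < alpha).
#'
#' @param interaction_fit `cox_result` of the full interaction model on
#'   the test data.
#' @param subgroup_fit `cox_result` of the treatment-only model fitted
#'   within the subgroup.
#' @param fdr Permutation FDR (from [permutation_fdr()], list or number).
#' @param alpha Significance level (default 0.05).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return A list: `criterion1`, `criterion2`, `validated` (logical; `NA`
#'   = indeterminate when a fit did not converge), `reasons` (character).
#' @export
harm_verdict <- function(interaction_fit, subgroup_fit, fdr,
                         alpha = 0.05, fdr_threshold = 0.05) {
  fdr_val <- if (is.list(fdr)) fdr$fdr else fdr
  if (!interaction_fit$converged || !subgroup_fit$converged) {
    return(list(criterion1 = NA, criterion2 = NA, validated = NA,
                reasons = "indeterminate: non-converged Cox fit"))
  }
  it <- cox_term(interaction_fit, "treatment_x_subgroup")
  st <- cox_term(subgroup_fit, "treatment")
  c1 <- it$hr > 1 && it$p < alpha && fdr_val < fdr_threshold
  c2 <- st$hr > 1 && st$p < alpha
  reasons <- character()
  if (!c1) {
    reasons <- c(reasons, sprintf(
      "criterion 1 failed: interaction HR %.3g, p %.3g, FDR %.3g",
      it$hr, it$p, fdr_val))
  }
  if (!c2) {
    reasons <- c(reasons, sprintf(
      "criterion 2 failed: within-subgroup treatment HR %.3g, p %.3g",
      st$hr, st$p))
  }
  list(criterion1 = c1, criterion2 = c2, validated = c1 && c2,
       reasons = if (length(reasons)) reasons else "validated")
}

#' Event-frequency report by subgroup and arm
#'
#' Tabulates participants and events in the 2x2 of subgroup membership by
#' treatment arm (plus overall rows), with percentages rounded to one
#' decimal — the layout of an observed-outcomes table.
#'
#' @param table A trial table (needs `arm`, `event_indicator`).
#' @param member Logical membership vector over rows of `table`.
#' @return A `data.frame` with columns `group`, `arm`, `n`, `events`,
#'   `percent`; `flagged_empty` attribute if the subgroup is empty.
#' @export
frequency_report <- function(table, member) {
  member <- as.logical(member)
  cell <- function(group, rows, arm_val) {
    r <- rows & table$arm == arm_val
    n <- sum(r)
    e <- sum(table$event_indicator[r])
    data.frame(group = group,
               arm = ifelse(arm_val == 1, "intensive", "standard"),
               n = n, events = e,
               percent = if (n > 0) round(100 * e / n, 1) else NA_real_)
  }
  out <- rbind(
    cell("overall", rep(TRUE, nrow(table)), 1L),
    cell("overall", rep(TRUE, nrow(table)), 0L),
    cell("subgroup", member, 1L),
    cell("subgroup", member, 0L),
    cell("remainder", !member, 1L),
    cell("remainder", !member, 0L)
  )
  if (!any(member)) {
    attr(out, "flagged_empty") <- TRUE
  }
  out
}

#' Number needed to harm at a horizon
#'
#' NNH = 1 / (Kaplan-Meier event probability at the horizon under
#' treatment minus the same under control), within the subgroup. With no
#' censoring before the horizon this reduces to the reciprocal crude risk
#' difference. A nonpositive risk difference is returned signed with a
#' `no_harm_at_horizon` flag rather than an error.
#'
#' @param table Trial table.
#' @param member Logical subgroup membership.
#' @param horizon Years; default the overall median follow-up time.
#' @return List: `nnh`, `risk_treated`, `risk_control`,
#'   `risk_difference`, `horizon`, `no_harm_at_horizon`.
#' @export
number_needed_to_harm <- function(table, member, horizon = NULL) {
  horizon <- horizon %||% median(table$event_time)
  sub <- table[as.logical(member), , drop = FALSE]
  if (sum(sub$event_indicator[sub$arm == 1L]) == 0 &&
      sum(sub$event_indicator[sub$arm == 0L]) == 0) {
    stop("no events in either arm of the subgroup; NNH undefined",
         call. = FALSE)
  }
  km_risk <- function(rows) {
    fit <- survival::survfit(
      survival::Surv(event_time, event_indicator) ~ 1, data = rows)
    s <- summary(fit, times = horizon, extend = TRUE)$surv
    1 - s
  }
  r1 <- km_risk(sub[sub$arm == 1L, , drop = FALSE])
  r0 <- km_risk(sub[sub$arm == 0L, , drop = FALSE])
  rd <- r1 - r0
  list(
    nnh = 1 / rd,
    risk_treated = r1,
    risk_control = r0,
    risk_difference = rd,
    horizon = horizon,
    no_harm_at_horizon = rd <= 0
  )
}

#' Adverse-event Cox models within subgroup and remainder
#'
#' Derives each participant's time to first adverse event of the named
#' type (censored at follow-up) and fits a treatment-only site-stratified
#' Cox model separately within the subgroup and within the remainder,
#' plus a companion frequency report.
#'
#' @param table Trial table.
#' @param adverse_events Adverse-event table (`id`, `event_type`, `time`).
#' @param member Logical subgroup membership over rows of `table`.
#' @param event_type Which event type to analyze (default `"AKI"`).
#' @param ties Tie handling for the Cox fits.
#' @return List: `subgroup` and `remainder` (`cox_result` or `NULL` when
#'   a side has no events), `frequencies` (frequency report on the
#'   adverse-event indicator).
#' @export
adverse_event_cox <- function(table, adverse_events, member,
                              event_type = "AKI", ties = "breslow") {
  ae <- adverse_events[adverse_events$event_type == event_type, ,
                       drop = FALSE]
  first <- if (nrow(ae) > 0) {
    stats::aggregate(time ~ id, data = ae, FUN = min)
  } else {
    data.frame(id = integer(), time = numeric())
  }
  t_ae <- first$time[match(table$id, first$id)]
  has_ae <- !is.na(t_ae) & t_ae <= table$event_time
  ae_time <- ifelse(has_ae, t_ae, table$event_time)
  ae_event <- as.integer(has_ae)
  member <- as.logical(member)

  fit_side <- function(rows) {
    if (sum(ae_event[rows]) == 0) {
      return(NULL)
    }
    fit_cox(ae_time[rows], ae_event[rows], table$arm[rows],
            strata = table$site_id[rows], ties = ties)
  }
  freq_tab <- table
  freq_tab$event_indicator <- ae_event
  freq_tab$event_time <- ae_time
  list(
    subgroup = fit_side(member),
    remainder = fit_side(!member),
    frequencies = frequency_report(freq_tab, member)
  )
}

#' Validate one subgroup hypothesis on the test partition
#'
#' Runs the full validation for one hypothesis: the interaction Cox model,
#' the within-subgroup treatment-only model, the permutation FDR, the
#' two-criterion verdict, the frequency report and NNH.
#'
#' @param test_table Raw test-partition trial table.
#' @param hypothesis A hypothesis from [distill_hypotheses()] (membership
#'   uses its frozen unit thresholds), or a logical membership vector.
#' @param n_permutations Permutations for the FDR (default 1000).
#' @param seed Permutation seed.
#' @param alpha,fdr_threshold Verdict thresholds.
#' @param horizon NNH horizon (default median follow-up).
#' @param ties Cox tie handling.
#' @return List: `membership` counts, `interaction`, `within_subgroup`
#'   (`cox_result`s), `fdr`, `verdict`, `frequencies`, `nnh`.
#' @export
validate_hypothesis <- function(test_table, hypothesis,
                                n_permutations = 1000L, seed = 1L,
                                alpha = 0.05, fdr_threshold = 0.05,
                                horizon = NULL, ties = "breslow") {
  member <- if (is.logical(hypothesis)) {
    hypothesis
  } else {
    subgroup_membership(hypothesis, test_table)
  }
  if (!any(member) || all(member)) {
    return(list(
      membership = sum(member),
      interaction = NULL, within_subgroup = NULL, fdr = NULL,
      verdict = list(criterion1 = NA, criterion2 = NA, validated = NA,
                     reasons = "degenerate subgroup (empty or universal)"),
      frequencies = frequency_report(test_table, member), nnh = NULL
    ))
  }
  interaction_fit <- fit_cox(test_table$event_time,
                             test_table$event_indicator,
                             test_table$arm, as.numeric(member),
                             strata = test_table$site_id, ties = ties)
  sub <- test_table[member, , drop = FALSE]
  within_fit <- tryCatch(
    fit_cox(sub$event_time, sub$event_indicator, sub$arm,
            strata = sub$site_id, ties = ties),
    error = function(e) NULL
  )
  fdr <- if (interaction_fit$converged) {
    permutation_fdr(test_table$event_time, test_table$event_indicator,
                    test_table$arm, as.numeric(member),
                    strata = test_table$site_id,
                    n_permutations = n_permutations, seed = seed,
                    ties = ties)
  } else {
    NULL
  }
  verdict <- if (is.null(within_fit) || is.null(fdr)) {
    list(criterion1 = NA, criterion2 = NA, validated = NA,
         reasons = "indeterminate: a required fit was unavailable")
  } else {
    harm_verdict(interaction_fit, within_fit, fdr, alpha, fdr_threshold)
  }
  nnh <- tryCatch(number_needed_to_harm(test_table, member, horizon),
                  error = function(e) NULL)
  list(
    membership = sum(member),
    interaction = interaction_fit,
    within_subgroup = within_fit,
    fdr = fdr,
    verdict = verdict,
    frequencies = frequency_report(test_table, member),
    nnh = nnh
  )
}
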