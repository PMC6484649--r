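# Synthetic SPRINT-like trial generator: baseline cohort, longitudinal BP
# visits, and adverse-event (AKI) times from a proportional-hazards model
# with a configurable planted harmful subgroup.

evaluate_rule <- function(rule, covariates) {
  if (length(rule) == 0L) {
    return(rep(FALSE, nrow(covariates)))
  }
  member <- rep(TRUE, nrow(covariates))
  for (cond in rule) {
    x <- covariates[[cond$covariate]]
    member <- member & switch(cond$op,
      gt = x > cond$value,
      le = x <= cond$value,
      eq = x == cond$value
    )
  }
  member
}

#' Generate a synthetic trial cohort
#'
#' Draws baseline covariates from the configured marginals, assigns
#' participants 1:1 to intensive vs standard arms and uniformly to clinic
#' sites, and draws time-to-first primary event from an exponential
#' proportional-hazards model with linear predictor
#' `global_log_hr * arm + subgroup_extra_log_hr * arm * member`, with an
#' optional log-normal per-site frailty on the baseline hazard. Censoring
#' is administrative: entry uniform over the accrual window, follow-up
#' capped at `study_years - entry`.
#'
#' True subgroup membership is attached as a sidecar (`attr(, "truth")`),
#' never as a column of the returned table, so downstream stages cannot
#' consume it by accident.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` with columns `id`, `site_id`, `arm` (1 =
#'   intensive, 0 = standard), one column per baseline covariate,
#'   `event_time` (years) and `event_indicator` (0/1), plus a
#'   `data.frame` attribute `truth` with `id` and `in_subgroup`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  with_seed(derive_seed(config$seed, "cohort"), {
    site_id <- sample(rep_len(seq_len(config$n_sites), n))
    arm <- sample(rep_len(c(0L, 1L), n))

    cov <- list()
    rho <- config$smoking_sbp_correlation
    nm <- vapply(config$covariate_spec, `[[`, "", "name")
    z_shared <- if (rho != 0) rnorm(n) else NULL
    for (cv in config$covariate_spec) {
      if (cv$kind == "continuous") {
        if (!is.null(z_shared) && cv$name == "sbp") {
          z <- rho * z_shared + sqrt(1 - rho^2) * rnorm(n)
          cov[[cv$name]] <- cv$mean + cv$sd * z
        } else {
          cov[[cv$name]] <- rnorm(n, cv$mean, cv$sd)
        }
      } else {
        if (!is.null(z_shared) && cv$name == "smoker") {
          cov[[cv$name]] <- as.integer(z_shared > qnorm(1 - cv$prevalence))
        } else {
          cov[[cv$name]] <- rbinom(n, 1L, cv$prevalence)
        }
      }
    }
    covariates <- as.data.frame(cov)

    member <- evaluate_rule(config$harm_subgroup_rule, covariates)
    lp <- config$global_treatment_log_hazard_ratio * arm +
      config$subgroup_extra_log_hazard_ratio * arm * member
    site_frailty <- if (config$site_frailty_sd > 0) {
      exp(rnorm(config$n_sites, 0, config$site_frailty_sd))
    } else {
      rep(1, config$n_sites)
    }
    rate <- config$baseline_hazard * site_frailty[site_id] * exp(lp)
    t_event <- rexp(n, rate)
    entry <- runif(n, 0, config$accrual_years)
    follow_max <- config$study_years - entry
    event_time <- pmin(t_event, follow_max)
    event_indicator <- as.integer(t_event <= follow_max)

    out <- data.frame(
      id = seq_len(n),
      site_id = site_id,
      arm = arm,
      covariates,
      event_time = event_time,
      event_indicator = event_indicator
    )
    attr(out, "truth") <- data.frame(
      id = seq_len(n),
      in_subgroup = as.integer(member)
    )
    out
  })
}

#' Generate longitudinal blood-pressure trajectories
#'
#' For each participant, SBP and DBP at each scheduled visit decay
#' exponentially from the baseline value toward the arm-specific target
#' (deeper by `subgroup_extra_drop` for treated subgroup members), plus
#' Gaussian visit noise. Visits are scheduled every `visit_interval` years
#' and stop at the participant's follow-up time. DBP is kept strictly
#' below SBP.
#'
#' @param cohort Output of [generate_cohort()] (the truth sidecar supplies
#'   subgroup membership for the trajectory target).
#' @param config The same [sim_config()] used to generate the cohort.
#' @return A `data.frame` with columns `id`, `visit_time` (years), `sbp`,
#'   `dbp` (mm Hg).
#' @export
generate_bp_trajectories <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$bp_trajectory_spec
  if (spec$visit_interval <= 0) {
    return(data.frame(id = integer(), visit_time = numeric(),
                      sbp = numeric(), dbp = numeric()))
  }
  truth <- attr(cohort, "truth")
  member <- if (!is.null(truth)) truth$in_subgroup == 1L else
    evaluate_rule(config$harm_subgroup_rule, cohort)
  with_seed(derive_seed(config$seed, "bp"), {
    arm_name <- ifelse(cohort$arm == 1L, "intensive", "standard")
    extra_sbp <- ifelse(cohort$arm == 1L & member, spec$subgroup_extra_drop[["sbp"]], 0)
    extra_dbp <- ifelse(cohort$arm == 1L & member, spec$subgroup_extra_drop[["dbp"]], 0)
    target_sbp <- spec$sbp_target[arm_name] - extra_sbp
    target_dbp <- spec$dbp_target[arm_name] - extra_dbp

    times <- seq(spec$visit_interval, config$study_years,
                 by = spec$visit_interval)
    n_vis <- vapply(cohort$event_time,
                    function(fu) sum(times <= fu), integer(1))
    idx <- rep.int(seq_len(nrow(cohort)), n_vis)
    visit_time <- unlist(lapply(n_vis, function(k) times[seq_len(k)]),
                         use.names = FALSE)
    if (length(idx) == 0L) {
      data.frame(id = integer(), visit_time = numeric(),
                 sbp = numeric(), dbp = numeric())
    } else {
      decay <- exp(-spec$decay_rate * visit_time)
      sbp <- target_sbp[idx] + (cohort$sbp[idx] - target_sbp[idx]) * decay +
        rnorm(length(idx), 0, spec$noise_sd)
      dbp <- target_dbp[idx] + (cohort$dbp[idx] - target_dbp[idx]) * decay +
        rnorm(length(idx), 0, spec$noise_sd)
      dbp <- pmin(dbp, sbp - 0.5)
      dbp <- pmax(dbp, 1)
      data.frame(id = cohort$id[idx], visit_time = visit_time,
                 sbp = sbp, dbp = dbp)
    }
  })
}

#' Generate adverse-event (AKI) times
#'
#' Draws time to first acute-kidney-injury event from an exponential
#' proportional-hazards model with hazard
#' `baseline * treatment_multiplier^arm * subgroup_treatment_multiplier^(arm * member)`,
#' censored at each participant's follow-up time; only observed events are
#' returned.
#'
#' @inheritParams generate_bp_trajectories
#' @param event_type Label written to the `event_type` column.
#' @return A `data.frame` with columns `id`, `event_type`, `time` (years).
#' @export
generate_adverse_events <- function(cohort, config, event_type = "AKI") {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$adverse_event_spec
  empty <- data.frame(id = integer(), event_type = character(),
                      time = numeric())
  if (spec$baseline_hazard <= 0) {
    return(empty)
  }
  truth <- attr(cohort, "truth")
  member <- if (!is.null(truth)) truth$in_subgroup == 1L else
    evaluate_rule(config$harm_subgroup_rule, cohort)
  with_seed(derive_seed(config$seed, "ae"), {
    rate <- spec$baseline_hazard *
      spec$treatment_multiplier^cohort$arm *
      spec$subgroup_treatment_multiplier^(cohort$arm * member)
    t_ae <- rexp(nrow(cohort), rate)
    keep <- t_ae <= cohort$event_time
    if (!any(keep)) {
      empty
    } else {
      data.frame(id = cohort$id[keep], event_type = event_type,
                 time = t_ae[keep])
    }
  })
}
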