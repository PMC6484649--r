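#' Default baseline covariate specification
#'
#' Marginal distributions for the 17 baseline characteristics of a
#' SPRINT-like hypertension cohort (persons aged 50+ with elevated systolic
#' blood pressure and increased cardiovascular risk): continuous covariates
#' as normal means/SDs, binary covariates as prevalences. Values follow the
#' published baseline table of that trial population.
#'
#' @return A list of covariate specifications, each a list with elements
#'   `name`, `kind` (`"continuous"` or `"binary"`) and either `mean`/`sd`
#'   or `prevalence`.
#' @export
default_covariate_spec <- function() {
  cont <- function(name, mean, sd) {
    list(name = name, kind = "continuous", mean = mean, sd = sd)
  }
  bin <- function(name, prevalence) {
    list(name = name, kind = "binary", prevalence = prevalence)
  }
  list(
    cont("framingham_risk", 20.1, 10.9),
    bin("smoker", 0.136),
    cont("sbp", 139.7, 15.6),
    cont("dbp", 78.2, 12.0),
    bin("aspirin", 0.511),
    cont("egfr", 71.7, 20.7),
    cont("creatinine", 1.1, 0.35),
    bin("black", 0.315),
    cont("age", 67.9, 9.4),
    bin("female", 0.356),
    cont("cholesterol", 190.0, 40.6),
    cont("glucose", 98.9, 13.6),
    cont("hdl", 52.8, 14.5),
    cont("triglycerides", 126.1, 84.0),
    cont("uacr", 42.5, 166.0),
    cont("bmi", 29.9, 5.8),
    bin("statin", 0.433)
  )
}

#' Simulation configuration for a SPRINT-like two-arm trial
#'
#' Bundles every knob of the synthetic-trial generator: cohort size and
#' site structure, baseline covariate marginals, an optional planted
#' harmful subgroup (a conjunction of covariate conditions whose members
#' receive an extra log-hazard-ratio under treatment), the exponential
#' event model, administrative censoring (uniform accrual plus a fixed
#' study end), an adverse-event (AKI) process, and per-arm blood-pressure
#' trajectory targets.
#'
#' Effect sizes here are simulation knobs, not estimates from any real
#' trial. Defaults emulate the emulated cohort's published scale: 9361
#' participants, ~100 clinic sites, a composite event probability near 6%
#' over a median 3.3 years of follow-up, accrual over 2.4 years.
#'
#' @param n_participants Cohort size.
#' @param n_sites Number of clinic sites (participants assigned uniformly).
#' @param covariate_spec List of covariate specifications as produced by
#'   [default_covariate_spec()].
#' @param harm_subgroup_rule Conjunction (list) of conditions, each a list
#'   `list(covariate=, op=, value=)` with `op` one of `"gt"`, `"le"`,
#'   `"eq"`, evaluated on the raw covariates. Empty list = no planted
#'   subgroup (global-effect null for the interaction).
#' @param baseline_hazard Exponential baseline hazard, events per
#'   person-year, in the standard arm.
#' @param global_treatment_log_hazard_ratio Log hazard ratio applied to
#'   every treated participant.
#' @param subgroup_extra_log_hazard_ratio Additional log hazard ratio for
#'   treated members of the planted subgroup.
#' @param accrual_years Uniform accrual window length, years.
#' @param study_years Time from start of accrual to administrative study
#'   end, years. Follow-up is censored at `study_years - entry_time`.
#' @param site_frailty_sd SD of the log-normal per-site baseline-hazard
#'   multiplier (0 = shared baseline hazard).
#' @param smoking_sbp_correlation Latent Gaussian correlation between the
#'   `smoker` indicator and `sbp`, to stress-test discovery when the
#'   subgroup-defining covariates are dependent.
#' @param adverse_event_spec List with `baseline_hazard` (AKI events per
#'   person-year), `treatment_multiplier` (hazard multiplier under
#'   treatment) and `subgroup_treatment_multiplier` (additional multiplier
#'   for treated subgroup members).
#' @param bp_trajectory_spec List with `visit_interval` (years between
#'   scheduled visits), per-arm `sbp_target`/`dbp_target` (named vectors
#'   with elements `intensive`, `standard`, mm Hg), `decay_rate` (per-year
#'   exponential approach to target), `subgroup_extra_drop` (named vector
#'   `sbp`, `dbp`: extra target reduction for treated subgroup members,
#'   mm Hg) and `noise_sd` (visit-level Gaussian noise, mm Hg).
#' @param seed Integer seed; every generator output is a deterministic
#'   function of (config, seed).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 9361,
                       n_sites = 100,
                       covariate_spec = default_covariate_spec(),
                       harm_subgroup_rule = list(),
                       baseline_hazard = 0.019,
                       global_treatment_log_hazard_ratio = 0,
                       subgroup_extra_log_hazard_ratio = 0,
                       accrual_years = 2.4,
                       study_years = 4.5,
                       site_frailty_sd = 0,
                       smoking_sbp_correlation = 0,
                       adverse_event_spec = list(
                         baseline_hazard = 0.02,
                         treatment_multiplier = 1.6,
                         subgroup_treatment_multiplier = 1
                       ),
                       bp_trajectory_spec = list(
                         visit_interval = 0.25,
                         sbp_target = c(intensive = 121, standard = 135),
                         dbp_target = c(intensive = 68, standard = 76),
                         decay_rate = 4,
                         subgroup_extra_drop = c(sbp = 0, dbp = 0),
                         noise_sd = 5
                       ),
                       seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop("n_participants must be a positive count", call. = FALSE)
  }
  if (baseline_hazard <= 0) {
    stop("baseline_hazard must be > 0", call. = FALSE)
  }
  if (adverse_event_spec$baseline_hazard < 0) {
    stop("adverse-event baseline_hazard must be >= 0", call. = FALSE)
  }
  if (accrual_years < 0 || study_years <= accrual_years) {
    stop("need 0 <= accrual_years < study_years", call. = FALSE)
  }
  nm <- vapply(covariate_spec, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate covariate names in covariate_spec", call. = FALSE)
  }
  for (cv in covariate_spec) {
    if (cv$kind == "continuous") {
      if (!is.finite(cv$mean) || !is.finite(cv$sd) || cv$sd < 0) {
        stop("invalid distribution parameters for covariate '", cv$name, "'",
             call. = FALSE)
      }
    } else if (cv$kind == "binary") {
      if (!is.finite(cv$prevalence) || cv$prevalence < 0 || cv$prevalence > 1) {
        stop("invalid prevalence for covariate '", cv$name, "'", call. = FALSE)
      }
    } else {
      stop("unknown kind for covariate '", cv$name, "'", call. = FALSE)
    }
  }
  for (cond in harm_subgroup_rule) {
    if (!cond$covariate %in% nm) {
      stop("harm_subgroup_rule refers to unknown covariate '",
           cond$covariate, "'", call. = FALSE)
    }
    if (!cond$op %in% c("gt", "le", "eq")) {
      stop("harm_subgroup_rule op must be one of gt/le/eq", call. = FALSE)
    }
  }
  if (bp_trajectory_spec$visit_interval < 0) {
    stop("visit_interval must be >= 0", call. = FALSE)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_sites = as.integer(n_sites),
      covariate_spec = covariate_spec,
      harm_subgroup_rule = harm_subgroup_rule,
      baseline_hazard = baseline_hazard,
      global_treatment_log_hazard_ratio = global_treatment_log_hazard_ratio,
      subgroup_extra_log_hazard_ratio = subgroup_extra_log_hazard_ratio,
      accrual_years = accrual_years,
      study_years = study_years,
      site_frailty_sd = site_frailty_sd,
      smoking_sbp_correlation = smoking_sbp_correlation,
      adverse_event_spec = adverse_event_spec,
      bp_trajectory_spec = bp_trajectory_spec,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Planted harmful-subgroup rule: current smokers with high baseline SBP
#'
#' Convenience constructor for the canonical stress-test subgroup — current
#' smokers whose baseline systolic pressure exceeds a threshold (by default
#' the top tercile of the default SBP marginal, ~146 mm Hg).
#'
#' @param sbp_threshold SBP cutoff in mm Hg.
#' @return A condition list usable as `harm_subgroup_rule`.
#' @export
smoker_high_sbp_rule <- function(sbp_threshold = qnorm(2 / 3, 139.7, 15.6)) {
  list(
    list(covariate = "smoker", op = "eq", value = 1),
    list(covariate = "sbp", op = "gt", value = sbp_threshold)
  )
}
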