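# End-to-end pipeline orchestration and tabular I/O.

#' Read a trial table from CSV
#'
#' Validates the required columns (`id`, `site_id`, `arm`, `event_time`,
#' `event_indicator`), positivity of times and 0/1 coding of arm and
#' event, and numeric covariates.
#'
#' @param path CSV path (header row, comma-delimited, "." decimal).
#' @return A validated trial `data.frame`.
#' @export
read_trial_table <- function(path) {
  tab <- read.csv(path)
  validate_trial_table(tab)
}

#' @rdname read_trial_table
#' @param table An in-memory trial table to validate.
#' @export
validate_trial_table <- function(table) {
  required <- .reserved_cols
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop("trial table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!table$arm %in% c(0L, 1L))) {
    bad <- which(!table$arm %in% c(0L, 1L))[1]
    stop("arm must be 0/1; offending row ", bad, call. = FALSE)
  }
  if (any(!table$event_indicator %in% c(0L, 1L))) {
    bad <- which(!table$event_indicator %in% c(0L, 1L))[1]
    stop("event_indicator must be 0/1; offending row ", bad, call. = FALSE)
  }
  if (any(table$event_time <= 0)) {
    stop("event_time must be > 0", call. = FALSE)
  }
  for (cv in covariate_columns(table)) {
    if (!is.numeric(table[[cv]])) {
      bad <- which(!grepl("^-?[0-9.eE+-]+$", as.character(table[[cv]])))[1]
      stop("non-numeric value in covariate '", cv, "' (row ",
           ifelse(is.na(bad), 1, bad), ")", call. = FALSE)
    }
  }
  table
}

#' Write a trial table (and optional truth sidecar) to CSV
#'
#' The hidden truth columns are written to a separate sidecar file so
#' downstream stages cannot accidentally consume them.
#'
#' @param table Trial table (possibly carrying a `truth` attribute).
#' @param path Output CSV path.
#' @param truth_path Optional path for the truth sidecar.
#' @export
write_trial_table <- function(table, path, truth_path = NULL) {
  write.csv(table, path, row.names = FALSE)
  truth <- attr(table, "truth")
  if (!is.null(truth_path) && !is.null(truth)) {
    write.csv(truth, truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' Baseline characteristics by arm
#'
#' Per-covariate means (SDs) within each arm plus a two-sample test
#' p-value — the standard randomization check table.
#'
#' @param table Trial table.
#' @return A `data.frame`: `covariate`, `mean_treated`, `sd_treated`,
#'   `mean_control`, `sd_control`, `p`.
#' @export
baseline_table <- function(table) {
  covs <- covariate_columns(table)
  rows <- lapply(covs, function(cv) {
    x1 <- table[[cv]][table$arm == 1L]
    x0 <- table[[cv]][table$arm == 0L]
    p <- tryCatch(stats::t.test(x1, x0)$p.value, error = function(e) NA_real_)
    data.frame(covariate = cv,
               mean_treated = mean(x1), sd_treated = sd(x1),
               mean_control = mean(x0), sd_control = sd(x0), p = p)
  })
  do.call(rbind, rows)
}

#' Run the full discovery-and-validation pipeline
#'
#' Orchestrates: simulate (or load) -> quantile discretization and
#' entropy-balanced split selection -> honest causal forest on the train
#' half -> harm-leaf harvest and hypothesis distillation -> Cox
#' interaction validation with permutation FDR on the test half ->
#' blood-pressure mechanism contrasts (when trajectories are available).
#' All stage seeds derive from the master seed, so a rerun with an
#' identical config reproduces every result exactly.
#'
#' @param config A list with components `sim` (a [sim_config()]; or
#'   supply `cohort` directly), `n_bins` (default 4), `n_split_candidates`
#'   (default 1000), `forest` (a [forest_params()]), `top_k`,
#'   `max_conditions`, `n_permutations`, `alpha`, `fdr_threshold`,
#'   `horizon`, `seed`.
#' @param outdir Optional output directory; when given, every artifact is
#'   written (cohort.csv, truth.csv, split_assignment.csv,
#'   cutpoints.json, balance_report.json, leaf_census.csv,
#'   hypotheses.json, validation_results.json, table2.csv,
#'   pressure_summary.csv, mechanism_contrasts.json, manifest.json).
#' @return A report bundle (list) with every stage's outputs.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  seed <- config$seed %||% 1L
  cohort <- config$cohort
  trajectories <- config$trajectories
  adverse <- config$adverse_events
  sim <- NULL
  if (is.null(cohort)) {
    if (is.null(config$sim)) {
      stop("config needs either a cohort table or a sim block",
           call. = FALSE)
    }
    sim <- config$sim
    sim$seed <- derive_seed(seed, "sim")
    cohort <- generate_cohort(sim)
    trajectories <- generate_bp_trajectories(cohort, sim)
    adverse <- generate_adverse_events(cohort, sim)
  }
  cohort <- validate_trial_table(cohort)

  n_bins <- config$n_bins %||% 4L
  candidates <- propose_and_score_splits(
    cohort, n_candidates = config$n_split_candidates %||% 1000L,
    seed = derive_seed(seed, "split"))
  split <- select_split(candidates)
  train <- cohort[cohort$id %in% split$train_ids, , drop = FALSE]
  test <- cohort[cohort$id %in% split$test_ids, , drop = FALSE]

  disc <- discretize_covariates(train, n_bins = n_bins)
  fp <- config$forest %||% forest_params()
  fp$seed <- derive_seed(seed, "forest")
  forest <- build_forest(disc$table, fp, disc$cutpoints)

  harm <- harvest_harm_leaves(forest)
  freq <- covariate_frequency(harm)
  hyps <- distill_hypotheses(
    harm, disc$cutpoints, train,
    max_conditions = config$max_conditions %||% 3L,
    top_k = config$top_k %||% 5L)

  validations <- lapply(seq_along(hyps), function(i) {
    validate_hypothesis(
      test, hyps[[i]],
      n_permutations = config$n_permutations %||% 1000L,
      seed = derive_seed(seed, paste0("perm", i)),
      alpha = config$alpha %||% 0.05,
      fdr_threshold = config$fdr_threshold %||% 0.05,
      horizon = config$horizon)
  })

  mechanisms <- NULL
  if (!is.null(trajectories) && nrow(trajectories) > 0 && length(hyps) > 0) {
    member <- subgroup_membership(hyps[[1]], cohort)
    if (any(member) && !all(member)) {
      mechanisms <- tryCatch(list(
        summary = summarize_pressures(trajectories, cohort, member),
        map = mechanism_contrast(trajectories, cohort, member, "map"),
        sbp = mechanism_contrast(trajectories, cohort, member, "sbp"),
        dbp = mechanism_contrast(trajectories, cohort, member, "dbp")
      ), error = function(e) NULL)
    }
  }
  adverse_results <- NULL
  if (!is.null(adverse) && nrow(adverse) > 0 && length(hyps) > 0) {
    member_test <- subgroup_membership(hyps[[1]], test)
    if (any(member_test) && !all(member_test)) {
      adverse_results <- tryCatch(
        adverse_event_cox(test, adverse, member_test),
        error = function(e) NULL)
    }
  }

  bundle <- list(
    cohort = cohort,
    trajectories = trajectories,
    adverse_events = adverse,
    split = split,
    candidates_scores = vapply(candidates, `[[`, numeric(1), "score"),
    cutpoints = disc$cutpoints,
    forest = forest,
    harm = harm,
    covariate_frequency = freq,
    hypotheses = hyps,
    validations = validations,
    adverse_results = adverse_results,
    mechanisms = mechanisms,
    sim_config = sim,
    seed = seed
  )
  if (!is.null(outdir)) {
    write_pipeline_artifacts(bundle, outdir)
  }
  invisible(bundle)
}

# Serialize the stage outputs of a run_pipeline() bundle. Numeric JSON is
# written at full precision so identical reruns are byte-identical.
write_pipeline_artifacts <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, file) {
    jsonlite::write_json(x, file.path(outdir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  write_trial_table(bundle$cohort, file.path(outdir, "cohort.csv"),
                    file.path(outdir, "truth.csv"))
  if (!is.null(bundle$sim_config)) {
    # the resolved simulation configuration, for provenance
    yaml::write_yaml(unclass(bundle$sim_config),
                     file.path(outdir, "config.yaml"))
  }
  write.csv(data.frame(
    id = c(bundle$split$train_ids, bundle$split$test_ids),
    partition = rep(c("train", "test"),
                    c(length(bundle$split$train_ids),
                      length(bundle$split$test_ids)))
  ), file.path(outdir, "split_assignment.csv"), row.names = FALSE)
  wj(bundle$cutpoints, "cutpoints.json")
  wj(list(scores = bundle$candidates_scores,
          selected = bundle$split$candidate,
          selected_score = bundle$split$score,
          smd = as.list(bundle$split$smd)), "balance_report.json")
  leaves <- bundle$forest$leaves
  write.csv(data.frame(
    tree = vapply(leaves, `[[`, integer(1), "tree"),
    leaf = vapply(leaves, `[[`, integer(1), "leaf"),
    tau_hat = vapply(leaves, function(l) l$tau_hat %||% NA_real_,
                     numeric(1)),
    n_estimation_treated = vapply(leaves, `[[`, integer(1),
                                  "n_estimation_treated"),
    n_estimation_control = vapply(leaves, `[[`, integer(1),
                                  "n_estimation_control"),
    path = vapply(leaves, function(l) {
      paste(vapply(l$path, function(c) {
        sprintf("%s %s %d", c$covariate, c$op, c$k)
      }, ""), collapse = " & ")
    }, "")
  ), file.path(outdir, "leaf_census.csv"), row.names = FALSE)
  wj(lapply(bundle$hypotheses, function(h) {
    h[c("label", "conditions", "n_leaves", "mean_tau_hat", "support",
        "rank")]
  }), "hypotheses.json")
  wj(lapply(bundle$validations, function(v) {
    list(
      membership = v$membership,
      interaction = if (!is.null(v$interaction)) {
        list(coefficients = v$interaction$coefficients,
             converged = v$interaction$converged)
      },
      within_subgroup = if (!is.null(v$within_subgroup)) {
        list(coefficients = v$within_subgroup$coefficients,
             converged = v$within_subgroup$converged)
      },
      fdr = v$fdr,
      verdict = v$verdict,
      nnh = v$nnh
    )
  }), "validation_results.json")
  if (length(bundle$validations) > 0) {
    write.csv(bundle$validations[[1]]$frequencies,
              file.path(outdir, "table2.csv"), row.names = FALSE)
  }
  if (!is.null(bundle$mechanisms)) {
    write.csv(bundle$mechanisms$summary,
              file.path(outdir, "pressure_summary.csv"), row.names = FALSE)
    wj(bundle$mechanisms[c("map", "sbp", "dbp")],
       "mechanism_contrasts.json")
  }
  wj(list(
    seed = bundle$seed,
    n_participants = nrow(bundle$cohort),
    n_trees = bundle$forest$params$n_trees,
    n_leaves = bundle$forest$n_leaves,
    harm_fraction = bundle$harm$harm_fraction,
    n_hypotheses = length(bundle$hypotheses)
  ), "manifest.json")
  invisible(outdir)
}
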