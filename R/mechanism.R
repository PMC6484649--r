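# Blood-pressure mechanism analyses: mean arterial pressure, per-visit
# group/arm pressure summaries, and the subgroup-vs-remainder contrast of
# treatment-group differences in mean on-treatment pressures.

#' Mean arterial pressure
#'
#' MAP = (SBP + 2 x DBP) / 3, mm Hg. Requires SBP > DBP > 0.
#'
#' @param sbp Systolic blood pressure, mm Hg.
#' @param dbp Diastolic blood pressure, mm Hg.
#' @return Mean arterial pressure, mm Hg.
#' @export
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(dbp <= 0) || any(dbp >= sbp)) {
    stop("require sbp > dbp > 0", call. = FALSE)
  }
  (sbp + 2 * dbp) / 3
}

#' Per-visit pressure summaries by subgroup and arm
#'
#' Joins the trajectory table to the cohort and computes cell means of
#' SBP, DBP and MAP for every (subgroup/remainder, arm, visit time) cell,
#' with the number of contributing participants.
#'
#' @param trajectories Blood-pressure visit table (`id`, `visit_time`,
#'   `sbp`, `dbp`).
#' @param cohort Trial table supplying `arm` per `id`.
#' @param member Logical subgroup membership over rows of `cohort`.
#' @return A `data.frame`: `group`, `arm`, `visit_time`, `mean_sbp`,
#'   `mean_dbp`, `mean_map`, `n`.
#' @export
summarize_pressures <- function(trajectories, cohort, member) {
  pos <- match(trajectories$id, cohort$id)
  if (anyNA(pos)) {
    orphans <- unique(trajectories$id[is.na(pos)])
    stop("trajectory ids absent from cohort: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  }
  member <- as.logical(member)
  df <- data.frame(
    group = ifelse(member[pos], "subgroup", "remainder"),
    arm = ifelse(cohort$arm[pos] == 1L, "intensive", "standard"),
    visit_time = trajectories$visit_time,
    sbp = trajectories$sbp,
    dbp = trajectories$dbp,
    map = mean_arterial_pressure(trajectories$sbp, trajectories$dbp)
  )
  agg <- aggregate(cbind(sbp, dbp, map) ~ group + arm + visit_time,
                   data = df, FUN = mean)
  cnt <- aggregate(cbind(n = sbp) ~ group + arm + visit_time,
                   data = df, FUN = length)
  out <- merge(agg, cnt, by = c("group", "arm", "visit_time"))
  names(out) <- c("group", "arm", "visit_time",
                  "mean_sbp", "mean_dbp", "mean_map", "n")
  out[order(out$group, out$arm, out$visit_time), , drop = FALSE]
}

#' Subgroup-vs-remainder contrast of treatment-group pressure differences
#'
#' For each participant, averages the chosen quantity (MAP, SBP or DBP)
#' over all post-baseline visits; the contrast is the
#' difference-in-differences
#' `(subgroup: intensive mean - standard mean) - (remainder: intensive
#' mean - standard mean)`, with a normal-theory 95% CI and p-value from
#' the summed variances of the four independent cell means. A deeper
#' pressure reduction in the subgroup therefore yields a negative
#' contrast.
#'
#' @param trajectories Blood-pressure visit table.
#' @param cohort Trial table.
#' @param member Logical subgroup membership over rows of `cohort`.
#' @param quantity `"map"` (default), `"sbp"` or `"dbp"`.
#' @return A list: `quantity`, `contrast` (mm Hg), `ci_lower`,
#'   `ci_upper`, `p`, `cells` (per-cell n, mean, variance).
#' @export
mechanism_contrast <- function(trajectories, cohort, member,
                               quantity = c("map", "sbp", "dbp")) {
  quantity <- match.arg(quantity)
  pos <- match(trajectories$id, cohort$id)
  if (anyNA(pos)) {
    stop("trajectory ids absent from cohort", call. = FALSE)
  }
  val <- switch(quantity,
    map = mean_arterial_pressure(trajectories$sbp, trajectories$dbp),
    sbp = trajectories$sbp,
    dbp = trajectories$dbp
  )
  per <- aggregate(val, by = list(id = trajectories$id), FUN = mean)
  names(per) <- c("id", "value")
  cpos <- match(per$id, cohort$id)
  member <- as.logical(member)
  per$group <- ifelse(member[cpos], "subgroup", "remainder")
  per$arm <- cohort$arm[cpos]

  cell_stats <- function(group, arm) {
    v <- per$value[per$group == group & per$arm == arm]
    if (length(v) < 2) {
      stop("cell ", group, " x arm ", arm,
           " has fewer than 2 participants; variance undefined",
           call. = FALSE)
    }
    list(n = length(v), mean = mean(v), var = stats::var(v))
  }
  s1 <- cell_stats("subgroup", 1L)
  s0 <- cell_stats("subgroup", 0L)
  r1 <- cell_stats("remainder", 1L)
  r0 <- cell_stats("remainder", 0L)
  est <- (s1$mean - s0$mean) - (r1$mean - r0$mean)
  se <- sqrt(s1$var / s1$n + s0$var / s0$n + r1$var / r1$n + r0$var / r0$n)
  z <- est / se
  list(
    quantity = quantity,
    contrast = est,
    se = se,
    ci_lower = est - qnorm(0.975) * se,
    ci_upper = est + qnorm(0.975) * se,
    p = 2 * pnorm(-abs(z)),
    cells = list(subgroup_intensive = s1, subgroup_standard = s0,
                 remainder_intensive = r1, remainder_standard = r0)
  )
}
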