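---
title: "Discovering and validating treatment-harm subgroups with honest causal forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating treatment-harm subgroups with honest causal forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmforest)
```

## The problem

A randomized trial with an overall beneficial intervention can still harm a
hidden subgroup. The canonical example motivating this package is intensive
systolic blood-pressure (SBP) control in hypertensive patients: lowering the
SBP target reduces composite cardiovascular events on average, yet raises
the plausible concern that patients with particular baseline profiles —
e.g. current smokers with high baseline SBP, whose high-pressure
vasculature may tolerate a large drop in perfusion pressure poorly — see
*more* events under the intensive target, along with treatment-associated
serious adverse events such as acute kidney injury (AKI).

Classical one-covariate-at-a-time subgroup analysis is underpowered and
multiplicity-ridden for this question. `harmforest` implements a
discovery-and-validation design instead:

1. **Balanced sample splitting.** The cohort is split 50/50 into a training
   and a testing half. Among many candidate random splits, the one whose
   training half is most nearly distribution-matched to the full sample —
   judged by entropy-balancing weights — is selected.
2. **Honest causal forest (training half).** Many shallow decision trees
   partition quantile-discretized baseline covariates to localize
   heterogeneity in the treatment–outcome association. Leaves with a
   positive honest estimate (higher event rate under treatment) are *harm
   leaves*.
3. **Hypothesis distillation.** Harm-leaf paths are canonicalized,
   deduplicated and ranked into a handful of candidate subgroup
   definitions with frozen original-unit thresholds.
4. **Validation (testing half).** Each hypothesis is tested with a
   site-stratified Cox model containing treatment, subgroup and their
   interaction; a permutation scheme estimates a false-discovery rate for
   the interaction; a two-criterion verdict declares the subgroup
   validated only if both the interaction and the within-subgroup
   treatment effect are adverse and significant.
5. **Mechanisms.** Event frequencies, number needed to harm (NNH),
   adverse-event (AKI) hazard ratios, and longitudinal blood-pressure
   contrasts (mean arterial pressure, MAP = (SBP + 2·DBP)/3) quantify how
   harm may arise.

Because the motivating trial's participant-level data are access-restricted,
the package ships a synthetic-trial generator that emulates a cohort of the
same shape, with an optional *planted* harmful subgroup whose true effect
size is known. Every stage of the pipeline is exercised against that
generator.

## The synthetic trial generator

`sim_config()` + `generate_cohort()` draw a two-arm (1:1) trial:

* **Scale.** Defaults: 9361 participants, 100 clinic sites, accrual
  uniform over 2.4 years, administrative study end at 4.5 years — giving a
  median follow-up near 3.3 years with follow-up between 2.1 and 4.5
  years.
* **Covariates.** 17 baseline covariates drawn from the published
  baseline-table marginals of the emulated hypertension cohort
  (`default_covariate_spec()`): normal for continuous (e.g. SBP
  139.7 ± 15.6 mm Hg, age 67.9 ± 9.4 y), Bernoulli for binary (e.g.
  current smoker 13.6%). Covariates are independent by default; an
  explicit `smoking_sbp_correlation` knob couples the subgroup-defining
  pair through a shared latent Gaussian to stress-test discovery under
  dependence.
* **Events.** Time-to-first composite event is exponential with baseline
  hazard 0.019 / person-year — chosen so the closed-form cumulative event
  probability 1 − exp(−0.019 × 3.3) ≈ 6% matches the 5–7% event fraction
  of the emulated trial — times `exp(global_log_hr · arm +
  extra_log_hr · arm · member)`, with an optional log-normal per-site
  frailty so site stratification in the validation stage has something
  real to absorb. Censoring is administrative only; no loss-to-follow-up
  process is modeled.
* **Truth sidecar.** True subgroup membership is attached as an attribute
  and written to a separate `truth.csv`, never as a cohort column, so
  downstream stages cannot consume it accidentally.
* **Adverse events.** AKI times are exponential with hazard
  `baseline · treatment_multiplier^arm ·
  subgroup_treatment_multiplier^(arm·member)`, censored at follow-up.
* **Blood pressure.** Visits every 3 months; SBP/DBP decay exponentially
  from baseline toward arm-specific targets (intensive 121/68, standard
  135/76 mm Hg), deeper by a configurable extra drop for treated subgroup
  members, plus visit-level Gaussian noise (SD 5 mm Hg). DBP is clamped
  strictly below SBP so MAP stays between the two.

All effect sizes are simulation knobs, not estimates from any real trial.
What the generator deliberately does **not** emulate: medication
titration, adherence dynamics, competing risks, informative censoring,
measurement error in covariates, or realistic covariate correlation
structure (beyond the single optional smoking–SBP coupling). Tests passing
against this generator therefore demonstrate correctness of the machinery
and calibration under clean conditions, not performance on real trial
data.

## Discretization and split selection

Continuous covariates are binned at empirical quantiles
(`discretize_covariates()`, default quartiles; terciles via `n_bins = 3`).
Conventions, fixed once and saved in the cutpoint map: linear-interpolation
quantiles (R type 7), half-open bins `(a, b]` so boundary values fall into
the lower bin. Any fixed convention preserves subgroup definitions once the
map is frozen; this one makes "top-tercile SBP" render as `sbp > cut`
with the cut equal to the empirical 2/3 quantile. Constant covariates
collapse to one bin with a warning and are excluded from splitting.

`propose_and_score_splits()` draws (by default) 1000 random half-splits
and scores each by `entropy_balance_score()`: entropy-balancing weights
are fitted on the train half so its weighted first moments of every
baseline covariate, the event indicator and the arm indicator match the
full-sample means, and the score is the Kullback–Leibler divergence of
those weights from uniform — zero exactly when uniform weights already
balance. The dual is a smooth convex program solved by BFGS on
centred/scaled moments to gradient norm < 1e-5; a target mean outside the
train half's convex hull makes the dual unbounded and the candidate is
discarded with an infinite sentinel. `select_split()` takes the argmin,
ties to the lowest candidate index. Only the train half is scored: in a
50/50 split the test half is the complement, so near-balance of one side
implies near-balance of the other. Second-moment matching was considered
and left out: with ~19 first moments at n ≈ 4700 the program is
comfortably feasible, while doubling the moment count makes infeasible
candidates common at smaller n.

## The honest causal forest

Each of `n_trees` (default 1000) trees:

1. draws 50% of the training data without replacement;
2. splits that subsample into a *structure* half and an *estimation* half
   (honesty — the alternative convention, using the whole subsample for
   structure and its complement for estimation, is available via
   `subsample_is_structure`);
3. grows recursively to `max_depth` 4: at each node every (covariate,
   ordinal threshold) pair is scored by the criterion
   `sum over children of n_child · tau_child²`, where `tau` is the
   treated-minus-control event-rate difference in the structure half.
   Maximizing this is algebraically the complement of minimizing the
   within-leaf squared error of a leaf-constant effect prediction, i.e.
   the split that most concentrates effect heterogeneity wins. A split is
   admissible only if all children retain ≥ 10 treated and ≥ 10 control
   participants in *both* halves, and is accepted only if it strictly
   improves on the unsplit node's score (so event-free data yield a single
   leaf);
4. estimates each leaf's `tau_hat` on the estimation half only.

The forest outcome is the plain binary event indicator: censoring is
deliberately ignored at the discovery stage (time-to-event handling
belongs to the Cox validation stage) — discovery errors from censoring
can only cost power, not validity, because validation is independent.
Ties among equal-scoring splits go to the first covariate in schema order,
then the lowest threshold, making forests bitwise reproducible; per-tree
seeds derive from the master seed so results are independent of execution
order. No random feature subsampling is used: every covariate is examined
at every node.

**Detection floor.** The criterion has no variance normalization, so at a
6% event rate the per-node noise scale of `n·tau²` (≈ 4·p·(1−p) for a
balanced split) dominates weak signals. A planted subgroup of ~5%
prevalence with an extra treated log-hazard of 0.7 changes a root-level
smoker split's tau by only ≈ 0.02 — well below that floor — so the
defining covariates of such a subgroup do *not* reliably top the harm-leaf
frequency ranking; with a stronger planted effect (extra log-hazard ≈ 2)
they rank first and second essentially always (see the test suite). Users
should read harm-leaf covariate frequencies as hypothesis generation, not
as evidence.

## From harm leaves to hypotheses

`harvest_harm_leaves()` keeps exactly the leaves with `tau_hat`
strictly > 0 (ties at zero count as benefit/neutral).
`covariate_frequency()` counts each covariate once per harm-leaf path.
`distill_hypotheses()` canonicalizes paths into per-covariate bin
intervals (contradictory conjunctions are dropped with a message),
truncates to the most frequent covariates, deduplicates, translates bins
into original units via the *training* cutpoint map, and ranks by number
of contributing leaves (ties by mean `tau_hat`; ranking by `tau_hat` is a
config alternative). The unit thresholds are then frozen: test-half
membership uses them directly, never re-derived quantiles, mirroring how a
clinical subgroup rule like "SBP > 144 mm Hg" would be carried forward.

## Validation

`fit_cox()` (backed by the survival package's partial-likelihood engine,
Breslow ties by default, Efron via config) fits the interaction model
`treatment * subgroup + strata(site)` and a treatment-only model within
the subgroup. Monotone likelihoods are flagged non-converged rather than
silently returned. `permutation_fdr()` permutes the subgroup label across
participants (arm, outcome and site fixed; within-site permutation was
considered and left as future config since site is a stratification
variable, not a confounder of the permuted label) and reports the
proportion of permuted interaction coefficients strictly greater than the
observed one. This quantity is formally a one-sided permutation p-value;
it is named FDR here because that is what the validation design calls it,
and the docs keep the note. Non-converged permutation fits count as not
exceeding (−Inf sentinel) and are tallied.

`harm_verdict()` applies the two criteria literally: (1) interaction
HR > 1 with two-tailed p < .05 and FDR < .05; (2) within-subgroup
treatment HR > 1 with p < .05. `frequency_report()` lays out the 2×2
(membership × arm) counts with one-decimal percentages, and
`number_needed_to_harm()` is 1 / (KM event probability at the horizon,
treated − control, within the subgroup), horizon defaulting to the median
follow-up. The reciprocal crude risk difference is recovered exactly when
nothing is censored before the horizon; a KM-based definition is used
because with administrative censoring the crude difference understates
per-horizon risk. Nonpositive risk differences return a signed value with
a `no_harm_at_horizon` flag.

With each hypothesis getting its own permutation FDR, no cross-hypothesis
correction is applied beyond the design itself — the split-sample
structure is the multiplicity control: the training half may dredge
freely, and the testing half sees only a handful of frozen hypotheses.
The suite checks the resulting guarantee directly: across 100 global-null
simulations the full pipeline validates a harm verdict in well under 10%
of runs, and the permutation FDR is uniform enough that `fdr < 0.05`
occurs in 5% ± 3 of null replicates. Power, by contrast, is a function of
the knobs: at a 6% event rate a test-half subgroup of ~230 participants
carries ~20 events, so the Wald SE of both the interaction and the
within-subgroup coefficient is ≈ 0.47, and an interaction log-hazard of
0.7 is detected at p < .05 only ~30% of the time. Validated verdicts at
that effect size are therefore sporadic; the pipeline's value at small
effects is ranking and effect estimation, not a reliable binary verdict.

## Mechanisms

`mean_arterial_pressure()` is the exact linear formula, so cell means of
MAP equal MAP of cell means to machine precision.
`summarize_pressures()` gives per (group, arm, visit) means;
`mechanism_contrast()` averages each participant's post-baseline visits
first (avoiding weighting participants by visit count — the aggregation
level is a package choice), then forms the difference-in-differences
(subgroup: intensive − standard) − (remainder: intensive − standard) with
a plain normal-theory CI from the four independent cell variances. No
repeated-measures correlation model is fitted; with hundreds of
participants per cell the large-sample CI is adequate for the contrast of
means, and a deeper subgroup reduction shows up as a negative contrast.

## Problem sizes and reproducibility

The shipped test suite runs the statistical property checks at sizes
chosen to make each check sharp but cheap: null calibration at n = 2000
with 200 permutations × 100 replicates, type-I error of the full pipeline
at n = 2000 with 100 trees and 100 permutations × 100 replicates,
planted-subgroup recovery at the full n = 9361 with 200 trees × 20 seeds.
The acceptance script (`scripts/acceptance.R`) re-runs the full pipeline
once at n = 9361 with 200 trees and 200 permutations. All randomness
flows from a single master seed through a documented per-stage derivation,
so identical configs reproduce every artifact byte-for-byte.

## Known limitations

* Discovery ignores censoring and time, by design; survival-aware
  splitting would be a genuine improvement.
* The split criterion's lack of variance normalization biases selection
  toward covariates with more candidate thresholds and away from binary
  covariates, and sets the detection floor described above.
* The permutation "FDR" controls error per hypothesis; dependencies among
  overlapping hypotheses are not modeled.
* The generator's covariate independence makes recovery tests
  interpretable but optimistic relative to correlated real-world baselines.
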