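---
title: "Scoring smartphone trail-making games as survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring smartphone trail-making games as survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jewelcox)
```

## The measurement problem

Smartphone "jewels" games are trail-making-style tasks: a screen shows a set
of jewels (the *level* is how many) and the player taps them in the required
order — numbered jewels for the simple task (`JEWELS_A`), alternating numbers
and letters for the task-switching variant (`JEWELS_B`). The raw data are a
timestamped sequence of touch events, each flagged correct or incorrect.

Summarising such a game with a single number is harder than it looks. Mean
inter-tap time ignores accuracy; accuracy ignores speed; both ignore the
sequential structure, and none of them are comparable across games with
different numbers of jewels. `jewelcox` instead treats each game as a small
survival experiment:

* the `L` jewels are the at-risk units, all entering at time 0 of the game;
* each correct tap is an *event* at its within-game time, so a completed
  game is exactly a Kaplan–Meier curve that steps down by `1/L` per tap;
* games of unequal level are made comparable by *administrative censoring
  based on the game level*: when a level-2 game is compared against a
  level-3 opponent, the level-2 game contributes its two events plus one
  censored pseudo-jewel at its completion time, so both sides carry the
  pairwise-maximum number of records.

Every game is then scored against a **reference path** — a pseudo-game whose
k-th tap time is the arithmetic mean of the k-th correct-tap times across
completed control games of the same type and level — by a two-group Cox
proportional-hazards fit. The exponentiated coefficient is the game's hazard
ratio (HR): `HR = 1` means reference-like tapping, `HR < 1` slower tapping
and hence a lower measured cognition value for that sitting.

```{r}
ref  <- list(level = 3, tap_times = c(1, 2, 3))      # reference path
slow <- list(level = 3, tap_times = c(2, 4, 6))      # uniformly slower
cox_fit(encode_pair(slow, ref))
```

## The pairwise Cox fit

With a single binary covariate (assessment vs reference) the Breslow log
partial likelihood reduces to

$$\ell(b) = d_1 b - \sum_{\text{events } i} \log\!\big(n_0(t_i) + n_1(t_i)e^{b}\big),$$

where $d_1$ counts assessment events and $n_0(t), n_1(t)$ are the risk-set
counts. $\ell$ is concave, so `cox_fit()` runs a damped Newton iteration on
the analytic score with a step-halving safeguard, and reports the standard
error from the observed information at the maximum. `partial_likelihood()`
exposes the objective itself (computed by direct risk-set summation) so that
brute-force grid maximisation can serve as an independent check; the test
suite verifies agreement to `1e-5` on hundreds of random datasets, and
cross-checks against `survival::coxph(..., ties = "breslow")`.

Numerical choices worth knowing:

* **Ties** are handled with the Breslow convention. For continuous tap
  clocks ties are measure-zero; they arise only in constructed examples.
  For the same reason `assemble_games()` rejects *decreasing* times but
  tolerates ties.
* **Monotone likelihoods.** A two-unit comparison with few events can
  separate (all assessment events before every reference event), making the
  partial likelihood monotone. `cox_fit()` detects this from the sign of the
  score at `±10` on the log-HR scale and refits with a weak ridge penalty
  (`λ = 0.1`), flagging the estimate `penalized = TRUE` rather than
  returning an infinite coefficient.
* **Identity.** Scoring any game against itself gives `|log HR| < 1e-6`; the
  Newton polish makes this exact to near machine precision.
* The Cox fit pools all events on calendar time since game start (no
  stratification by tap index): this is the most direct reading of taps as
  event times, and is what makes the reference's own ratio exactly 1.
* **Rank-invariance.** The partial likelihood depends on the two units'
  event times only through their interleaving. Uniformly slowing an
  assessment lowers its HR exactly when the slowdown re-interleaves the
  sequences; a time change that preserves all ranks leaves the HR
  untouched, and a slowdown extreme enough to separate the units entirely
  pushes the fit into the penalised regime where the HR no longer responds
  to further slowing. The monotonicity checks therefore use fixtures whose
  interleaving demonstrably changes at every scale factor tested.

A worked triple mirroring the package's running example: a level-3 reference
(taps at 1, 2, 3 s); game C at the same level but uniformly slower (2, 4,
6 s); game B at level 2, slower per tap (1.5, 3 s) yet finishing exactly
with the reference, comparable only through censoring:

```{r}
games <- fig2_fixture()
refs  <- build_reference_set(games[games$subject_id == "control", ])
score_all(games, refs)[, c("game_id", "level", "hr")]
```

The fitted ordering `HR_C < HR_B < 1` reproduces the qualitative ranking the
method is designed for: C is worse than B, and both are below the reference.

## From hazard ratios to beta values

Raw log hazard ratios still drift with difficulty level and with mistakes.
`fit_adjustment()` fits

```
log_hr ~ level + mistake_cat + (1 | subject_id)
```

by REML (`lme4`), weighting each observation by `1/se^2`, and `adjust()`
translates every estimate to a common baseline level (default: the modal
control level) and the zero-mistake category. The mistake count enters as a
three-level factor — none, one, more than one — so games with identical tap
times but 2 vs 7 errors are deliberately scored identically; the pairwise
two-unit Cox fit cannot identify a per-game mistake effect, which is why the
correction lives here. With a single observed level the slope is fixed at 0
(identity adjustment, with a warning); with a single subject the random
intercept is inestimable and the fit falls back to weighted least squares.

Per subject (and per assessment type — the two tasks are never pooled), the
adjusted values are combined by fixed-effect inverse-variance weighting into
the **beta value**

$$\beta = \frac{\sum_i v_i/\mathrm{se}_i^2}{\sum_i 1/\mathrm{se}_i^2},
  \qquad \mathrm{Var}(\beta) = \Big(\sum_i 1/\mathrm{se}_i^2\Big)^{-1},$$

the minimum-variance convex combination of the per-game estimates. Weekly
betas use the same formula within 7-day windows anchored at each subject's
*first observed game* — change is tracked relative to the subject's own
baseline, not the calendar — and reuse the study-wide adjustment model
(cheap windowed updates rather than per-week refits). Weeks without games
are missing, never zero. Weighting uses the per-game Cox standard errors,
the natural per-estimate precision.

When weekly betas are to be *correlated with other weekly streams* (surveys,
step counts collected on a common schedule), per-subject anchors would put
the betas on a week grid out of phase with the streams and attenuate every
correlation; pass a common origin via `weekly_betas(..., anchor = )` (or
`analyze_study(..., anchor = )`) so both sit on the same grid.

## Group comparison and cross-stream correlations

`compare_groups()` applies Welch's two-sample t-test to per-subject
study-wide betas (a Wilcoxon alternative sits behind `test = "wilcoxon"`);
`weekly_correlations()` builds, for one subject, the matrix of pairwise
Pearson correlations across weekly streams — weekly betas, survey scores,
step counts — over pairwise-complete weeks, reporting the per-cell overlap
and leaving any cell with fewer than 3 shared weeks missing. No
multiple-testing correction is applied across the matrix; it is an
exploratory display.

## What the synthetic generator emulates — and what it does not

`simulate_study()` generates complete studies against which every stage is
testable. Within a level-`L` game the `L` inter-tap gaps are exponential
with log rate

```
log(base_tap_rate) + level_effect * L + group effect + subject effect
                   [+ weekly cognition offset]
```

so the constant-hazard base case is exactly the model under which the Cox
encoding is correctly specified (a Weibull departure can be emulated by the
weekly offsets but is not a default). Defaults encode the study conditions
the pipeline targets: 17 controls and 18 patients over 12 weeks; controls
averaging 8 games per task over the study (rate 8/12 per week) while
patients complete roughly three times as many (2/wk on the simple task,
22/12 per week on task switching) — the adherence asymmetry matters because
weekly windows behave differently at different engagement levels; a patient
log-hazard shift of 0 on the simple task and −0.8 on task switching;
between-subject sd 0.3; a 5% per-tap mistake probability; levels drawn from
{2,…,5} with weights (.2, .3, .3, .2); and a 0.5 taps/s base rate (2 s mean
inter-tap gap). These are chosen as plausible magnitudes for this class of
task, not estimates of any particular dataset. Weekly step-count and
survey streams can be linearly coupled to the weekly cognition offset
(`step_coupling`, `survey_coupling`; default uncoupled).

Features of real data the generator does *not* emulate: reaction-time
distributions with refractory periods or speed–accuracy trade-offs,
learning/practice effects across weeks, missingness that is informative of
symptom state, or demographic structure. Passing tests therefore show the
pipeline is correct *under its own model*, not that the model captures
every behavioural nuance.

One property of the scoring deserves emphasis when interpreting betas: the
hazard ratio of a whole game against a *path* amplifies a per-tap log-rate
shift (a uniformly slower game also faces depleted reference risk sets), so
the group difference in mean beta is a monotone, roughly linear transform of
the injected per-tap effect with slope above 1 — the estimator separates
groups reliably but is not a calibrated estimate of the per-tap log-rate
shift itself. The parameter-recovery checks accordingly assert sign,
significance pattern, and type-I calibration, not unit-slope recovery.

## Problem sizes used in the checks

The test suite runs the full pipeline at the default study conditions
(17/18 subjects, 12 weeks, ≈1100 games per study) for 300 effect replicates
plus 300 null replicates (task-switching stream only) for the calibration
band; the Newton-vs-grid oracle uses 200 random two-game datasets with
levels ≤ 4; the coupling check uses one simulated study with weekly
cognition sd 1.5, noiseless step coupling, and ≈4 task-switching games per
patient-week — strong coupling chosen so the weekly beta's estimation noise
(pooled se ≈ 0.4) leaves the true weekly correlation near 0.98.

## Known limitations

* Games with the same Kaplan–Meier curve and mistake category are
  indistinguishable by construction.
* The reference path is a smooth average; individual games compared against
  it acquire a small positive mean log HR even for control subjects. This
  cancels in group contrasts and within-subject weekly changes, which is
  how betas are meant to be used.
* Incomplete games are excluded from scoring by default
  (`censor_incomplete = TRUE` scores them with censoring at the last
  observed tap); an incorrect touch does not reset the trail.
* Leave-one-out reference construction for control subjects is available
  (`leave_one_out = TRUE` in `analyze_study()`) but off by default; with
  pooled references each control contributes a small share of its own
  reference.
* Censoring is applied to the pairwise maximum level of each comparison;
  pass `max_level` to `encode_pair()` to censor against a global maximum
  instead.
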