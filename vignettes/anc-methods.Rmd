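---
title: "Lick microstructure and anticipatory negative contrast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lick microstructure and anticipatory negative contrast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anclick)
```

## The paradigm and its data

Anticipatory negative contrast (ANC) is the progressive suppression of
consumption of a less-preferred reward on occasions when a more-preferred
reward is predicted to follow. The paradigm this package analyses presents a
rat with two drinking phases per daily session: phase 1 (5 min, a 2%
maltodextrin + 0.2% saccharin solution, "Malt"), a 20-s inter-phase interval
(IPI) with both sippers retracted, and phase 2 (5 min). On *control* days
(`MM`) phase 2 contains the same Malt solution; on *experimental* days (`MC`)
it contains a 50:50 maltodextrin–condensed-milk solution ("CM"), signalled
either by the context the animal is placed in or by a flavor added to the
phase-1 solution. A control day and the following experimental day form one
*paired session*; cohorts run 8 paired sessions, with diet (free-fed `FF` vs
food-restricted `FR`) and predictor type (`context` vs `flavor`) as
between-subject factors, counterbalanced sipper sides, and CS+ assignment
recorded in a cohort manifest.

The raw material is an event log per animal per day: timestamps (seconds from
house-light onset) of individual licks (contact lickometer), port entries
(infrared beam breaks), and optionally the sipper extension/retraction events
that delimit the phases. All analysis windows are half-open `[start, end)`,
so a boundary event belongs to the following window and no event is counted
twice. When a log carries no sipper events the fixed schedule
`[0, 300), [300, 320), [320, 620)` is assumed.

The package defines its own tidy CSV event dialect (`events.csv`,
`cohort.csv`; see `read_events()`). Native acquisition formats are out of
scope by design: a converter from an operant-chamber system (e.g. MED-PC
output) only needs to emit this dialect to plug into the pipeline unchanged.

## Lick microstructure

Licking is segmented into **clusters**: maximal runs of licks with no
internal inter-lick interval (ILI) exceeding 500 ms. The inequality is
strict — a gap of exactly 500 ms stays inside a cluster — because the
criterion is stated as an upper bound on within-cluster ILIs ("no intervals
greater than"), and ties at a measured boundary should not split. Single
licks count as clusters of size 1; runs-of-licks definitions do not exclude
them, and an optional `min_cluster_size` argument exists for sensitivity
analyses rather than as a default filter.

Three quantities summarise each phase:

* **total licks** — consumption;
* **total clusters** — number of drinking bouts, which tracks the incentive
  value ("wanting") of the solution;
* **licks per cluster** — mean bout length, `total_licks / total_clusters`,
  which tracks palatability ("liking"). It is *missing*, not zero, for an
  animal-phase with no clusters, and group summaries average the per-animal
  values rather than pooling clusters, matching per-animal repeated-measures
  error terms.

Premature port entries (entries into the port whose sipper is not extended)
are a second anticipation measure, counted per phase, and separately per
port during the IPI. Licks recorded at the inactive port are hardware noise:
they are excluded from phase totals but counted and warned about, and licks
outside all windows are tallied in an audit table, so every recorded lick is
accounted for (`compute_metrics()` attribute `audit`).

## Contrast normalization

For each animal, session, phase and metric, the experimental-day value is
divided by the paired control-day value (`normalized_licks()`). A ratio of 1
means no contrast; values below 1 in phase 1 are the ANC signature. The
ratio is scale-invariant, undefined (flagged, row retained) when the control
value is zero, and the control day always precedes the experimental day
within a pair — the design does not counterbalance within-pair order.

## Statistical battery

Per group, metric and phase, a two-way fully within-subject ANOVA tests
Condition (`MM`/`MC`), Session (1–8) and their interaction, each against its
own subject-by-effect error stratum (`rm_anova_2way()`, base R `aov()` with
explicit `Error()` terms). Animals with incomplete cells are removed
listwise with a warning. Per-session Bonferroni-corrected paired t tests
(`bonferroni_posthoc()`, family size = number of sessions, one family per
metric-phase) locate *when* the contrast emerges; `emergence_session()`
reports the first significant session.

Across groups, the normalized phase-1 total licks enter a three-way mixed
ANOVA (`mixed_anova_3way()`): Diet and Predictor between subjects, Session
within. Between effects are tested on the subject stratum, within effects on
the subject-by-session stratum with **Greenhouse–Geisser** corrected degrees
of freedom. Epsilon is computed from the covariance of the session measures
pooled within between-group cells, via an orthonormal contrast `C`:
`eps = tr(C S C')^2 / (q tr((C S C')^2))`. It is exactly 1 for 2-level
factors and under compound symmetry, and bounded below by `1/q`. By default
the correction is applied only in the three-way model (`gg_correction =
"three_way_only"`), mirroring the convention of reporting integer df for the
two-factor within models and fractional df for the cross-group Session
terms; `"always"` and `"never"` are available. Note that the corrected p
exceeds the uncorrected p only where the test has signal (F in the rejection
region); for F near 1 shrinking both degrees of freedom can slightly lower
the tail probability. This is a property of the F distribution, not of the
implementation.

The unpaired t test defaults to the pooled-variance (Student) form with a
Welch option, since classical ANC reports use Student's form unless stated
otherwise. Degenerate inputs follow fixed conventions: zero variance with
equal means gives `t = 0, p = 1`.

The flavor preference test (10 forced-choice trials, then 30 free-choice
trials, pre and post conditioning) is summarised per epoch, trial type and
flavor, with CS+/CS− labels joined from the manifest, and analysed with the
same two-way within-subject machinery (epoch × CS role).

## The generative simulator

Every stage is exercisable without external data through a generative model
of the paradigm (`sim_params()`, `simulate_cohort()`):

* Cluster onsets arrive as a homogeneous Poisson process at rate `lambda`
  (clusters/min; Malt default 8, CM default 12).
* Cluster sizes are `1 + Poisson(mu - 1)` licks (mean `mu`; Malt default 6,
  CM default 12).
* Within-cluster ILIs are gamma (mean 0.14 s, shape 8), truncated below the
  500 ms threshold; the 0.14 s mean reflects typical ~7 Hz rodent licking.
  No quantitative lick-rate or cluster-size values are established for
  these particular solutions, so the defaults are field conventions,
  documented as such, not estimates of any dataset.
* Inter-cluster pauses are `threshold + Exponential(mean 2 s)`, so every
  generated pause exceeds the threshold and every within-cluster gap stays
  below it: segmentation recovers the generative partition exactly, which is
  what makes parameter recovery a sharp test. An onset that would collide
  with the previous cluster is deferred to the end of that pause; onsets
  pushed past the window end are dropped and clusters are truncated at the
  boundary, so no lick is ever emitted outside its window.
* On experimental days, phase-1 licking is suppressed by a logistic learning
  curve `s(session) = A * logistic((session - s0) / tau)` (defaults A = 0.4,
  s0 = 4, tau = 1), emulating the progressive divergence over sessions.
  The suppression is *split* between the two channels by the palatability
  share `rho`: cluster size is scaled by `1 - s*rho` and cluster rate by
  `1 - s*(1-rho)`. `rho = 1` reproduces the contextual-predictor signature
  (licks per cluster changes, cluster count does not); `rho = 0` the
  flavor-predictor signature (total licks change through cluster count
  only); the default 0.5 spreads the effect across both. Expected phase-1
  total licks are `duration_min * lambda_eff * mu_eff`.
* Premature entries to the phase-2 port arrive at `entry_rate_base` (1/min)
  plus `s(session) * entry_rate_anticipatory` (4/min) on experimental days
  during phase 1 and the IPI; all other non-active-port entries arrive at
  the baseline rate. These rates are conventions chosen to give a few
  baseline entries per phase and a clear learned anticipation signal.
* Reproducibility: one master seed; every (animal, day) stream draws from
  its own derived substream, so adding animals or sessions never perturbs
  existing streams, and identical parameters + seed give identical logs.

What the simulator does *not* model — and therefore what passing tests do
not establish about real data: within-session satiation or post-ingestive
feedback (rates are stationary within a phase), bout-pause hierarchies
beyond the single 500 ms criterion, flavor neophobia in the preference test,
session-to-session baseline drift, and individual-animal heterogeneity in
`mu`/`lambda` (between-animal variance arises only from sampling noise).
Calibration results (e.g. the 5% null rejection rate) are statements about
this generative model, not about any deposited dataset.

## Numerical and design choices

* Windows half-open everywhere; boundary events belong to the next window.
* Out-of-order timestamps are sorted with a warning (hardware logs can
  interleave channels); negative timestamps are hard errors.
* The number of paired sessions is configurable (default 8, the figure-axis
  convention of the experiment family this emulates).
* Epsilon uses the pooled within-cell covariance in the mixed model; in the
  fully-within model each term gets its own contrast covariance
  (`kronecker` products of per-factor contrasts).
* Sums of squares are sequential (`aov`); the between-subject design is
  expected balanced, and unbalanced cells trigger a warning.
* Stage outputs carry a provenance header (`# anclick <version>
  config_hash=... seed=...`) and no timestamps, so byte-identical reruns are
  the determinism check.
* Problem sizes used by the shipped verification code: the segmentation
  oracle runs 1,000 random trains up to 10^4 licks; the ANOVA oracle 50
  random balanced tables; the null calibration 2,000 simulated cohorts of
  10 animals; regime dissociation 100 cohorts per regime; parameter recovery
  one 20-animal cohort. These sizes make the binomial/simulation error small
  relative to the tolerances tested.

## Known limitations

* The three-way model assumes a balanced between design; severely unbalanced
  cohorts should use a mixed-effects model instead (out of scope here).
* No Huynh–Feldt correction and no effect-size measures are provided.
* The preference-test analyser requires the canonical 10 + 30 trial
  structure; irregular protocols are rejected rather than coerced.
* `licks_per_cluster` group means weight animals, not clusters; with very
  few clusters per animal the per-animal ratio estimator is noticeably
  noisier than a pooled estimator.
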