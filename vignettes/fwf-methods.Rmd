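---
title: "Workload footprints, generalized ACWR and imbalanced injury-risk evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Workload footprints, generalized ACWR and imbalanced injury-risk evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fwfoot)
```

## The problem and the data model

Sports-science staff monitor the external workload of athletes — distances,
speeds, accelerations, player load and similar GPS-derived quantities — to
manage training monotony and the risk of non-contact muscle injury. The
classical instrument is the acute:chronic workload ratio (ACWR): the load
accumulated over the last week (acute, "fatigue") divided by a rolling
average over the last month (chronic, "fitness"). Ratios far above 1 flag
an abrupt load spike.

`fwfoot` models a season as three aligned tables: workload records (one row
per player, event, variable and non-negative value), an event calendar
(training or match, with a match-day offset tag MD-k where MD-1 is the last
training before a match) and an injury report. From these it builds, per
player, the *workload footprint*: a variables × events matrix `X` with
`X[v, j]` the value of variable `v` at event `j`. Two missing-event
policies exist, because participation is inferred from record presence: a
zero-filled footprint keeps every calendar event as a column (absent =
zero load), an omission footprint drops events the player did not take part
in. Event indices are 0-based and gap-free; dates are metadata. All window
arithmetic counts *events*, not calendar days — "7" means the last seven
recorded sessions and matches. A calendar-day mode is deliberately out of
scope: every operator indexes events, and the weekly/four-weekly windows of
practice are event windows in a regular microcycle.

## Rolling operators

For a per-event series `x` the package provides:

* **tau-acute workload** `AW(j, tau)` — the rolling sum of the last `tau`
  events ending at `j`; `tau = 7` recovers the classical weekly acute load.
* **Chronic workloads** `CW28(j) = AW(j, 28) / 4` (coupled: the acute week
  is included) and `CW21(j) = (AW(j, 28) − AW(j, 7)) / 3` (uncoupled: the
  acute week is excluded, removing the numerator/denominator coupling).
* **Three ACWR variants** — coupled `AW7/CW28`, uncoupled `AW7/CW21`, and
  an EWMA form, the ratio of span-7 to span-28 exponentially weighted
  moving averages with weight `lambda = 2/(N + 1)` and first-value
  initialisation (the fixed point of a constant series; a zero
  initialisation is available). A zero chronic denominator is a legitimate
  pre-season state, so the ratio is returned as `NaN` — a tagged undefined
  value — never an exception and never a silent zero.
* **delta-ACW** `AW(j, tau) − AW(j−1, tau)`, which telescopes exactly to
  `x(j) − x(j − tau)`. The implementation evaluates the telescoped form
  directly, so the value is exact rather than a difference of two rounded
  sums; the equality of both forms is verified property-style in the test
  suite over a thousand random series.

Stacking these over a window set `T` gives the two feature blocks: the
cumulative block (every `AW(v, j, tau)`) and the temporal block (every
`deltaACW(v, j, tau)`), stored as variables × events × windows arrays with
explicit axis labels, since the flattened variables × (events · windows)
print layout leaves the ordering ambiguous. At the season start the
operators default to a zero-pad edge policy — earlier events contribute
zero load, matching the zero-fill participation convention — with a strict
policy available that raises on incomplete history instead.

## Dataset variants and pre-match undersampling

Five dataset designs turn a season into a labelled sample × feature table:
raw per-event values on participated events only (the baseline with no
feature engineering), one (acute, chronic, ratio) triplet per variable for
each of the three ACWR variants on a zero-filled calendar, and the full
footprint variant with the (AW, deltaACW) pair per variable and window.
Columns are named `{variable}__{operator}__{tau}` so every table is
self-describing. Undefined ratios are encoded as 0 in assembled tables
because tables guarantee no missing values; the operator-level `NaN` tag is
the place to detect them. The variant tables do not append the raw current
day's values to the footprint features; the two blocks alone define the
variant.

The prediction moment is MD-1, the last training before a match, so the
evaluation tables are undersampled to exactly those rows: only MD-1 samples
of players who participated in the following match are retained, and an
injury realized on match day is relocated to its MD-1 sample. Injuries at
other events (rare training-day cases) are dropped with a message; a match
with an injury but no tagged MD-1 predecessor drops the label with a
warning.

## Evaluation pipeline

The pipeline mirrors standard imbalanced-classification practice:

* **Robust-PCA outlier removal.** Rows are scored in a principal subspace
  (the smallest one explaining 80% of variance, median-centered) by a
  robust Mahalanobis score distance — MCD covariance of the scores — plus
  the orthogonal residual distance, each normalized by its median; the top
  `ceiling(f · n)` rows are removed. The literature names the method but
  not a unique algorithmic variant; this score-distance/orthogonal-distance
  combination is the conventional one.
* **Temporal split** (default 80/20) in event order with no shuffling, so
  the test period is a genuinely later season segment at natural
  prevalence.
* **SMOTE** on the training split only: synthetic minority samples are
  convex combinations of a minority row and one of its k (default 5)
  minority-class nearest neighbors.
* **PCA** fitted on the training split only, deliberately without
  standardization (the workload variables share comparable scales and
  their variances are physically meaningful), keeping the smallest number
  of components reaching 95% cumulative explained variance; the test split
  is projected with the train transform.
* **10-repeated stratified 2-fold cross-validation** over eight classifier
  families (LDA, logistic regression, naive Bayes, KNN, RBF-kernel SVM,
  CART, random forest, MLP — each a thin wrapper over the standard R
  implementation, seeded for reproducibility). Stratification deals each
  class round-robin, so per-fold class counts differ by at most one.
* **Metrics** suited to imbalance: ROC-AUC (rank statistic), PR-AUC (step
  integration) with the prevalence as its random-classifier floor, G-mean,
  accuracy, and Type I / Type II error (false-positive and false-negative
  rate at a 0.5 score threshold; the curve metrics are threshold-free).
  Repeated-run distributions are summarized by Student-t 95% confidence
  intervals.
* **Permutation testing** with the add-one estimator
  `p = (1 + #(null ≥ observed)) / (n + 1)`, which cannot return zero and
  makes the p-value exactly uniform under the null.
* **Bias-variance decomposition** of the 0-1 loss over bootstrap resamples
  of the training set: the main prediction is the per-test-point majority
  vote, bias its loss against the truth, variance the mean disagreement
  with it.

## The synthetic season generator

Real club seasons are private, so the generator produces seasons with the
statistical structure the method assumes: repeated microcycles
(MD-4 … MD-1, MD), per-variable lognormal loads (positive and right-skewed,
like real load metrics) shaped by the training week — heavier on MD-3 and
match day, lighter on MD-1 — occasional multiplicative spikes, and a
match-day injury hazard `plogis(beta0 + beta1 · z)` where `z` is the
standardized difference of the driver variable between MD-1 and `driverTau`
events earlier. The intercept is calibrated by bisection so the mean hazard
hits a target prevalence; only match participants are at risk, since
non-contact muscle injuries concentrate overwhelmingly in matches.

Two presets exist. `paper_scale` (23 players, 45 weeks, 73 variables,
participation 0.8, prevalence 0.028, slope 1.5) reproduces the regime of a
full elite season: roughly 4,100 player-event samples and on the order of
20–25 injuries. `smoke_test` (6 players, 8 weeks, 5 variables) is a
positive control for the pipeline: its prevalence (0.15) and hazard slope
(5) are deliberately strong, because at ~43 undersampled samples with ~6
positives a realistic effect size leaves even an oracle test on the true
driver feature underpowered; the preset exists to verify that the
differential features recover planted signal, not to claim realistic
effect sizes. The generator is a statistical stand-in, not a calibrated
emulator of real GPS data: it reproduces positivity, skew, microcycle
shape, imbalance and spike-driven hazard, but no biomechanical structure,
no injury-recurrence dynamics and no inter-variable correlation beyond the
shared spikes — so passing tests demonstrate the machinery and the
recoverability of differential signal, not field performance.

## Numerical and design choices

* Ties in ROC ranks use midranks; PR integration collapses tied scores.
* Stochastic families are seeded per fit; fold shuffles, SMOTE draws,
  permutations and bootstrap resamples are seeded independently of the
  classifier's own seeding, so identical configuration plus seed gives an
  identical report end to end.
* Double sessions (two events on one date) are accepted but must be
  pre-ordered in the input; the package does not guess an intra-day order.
* The per-event `history_complete` notion is implicit: with the strict
  edge policy any operator raises on incomplete history, which callers can
  use to mask warm-up events.
* Degenerate inputs: single-class folds flag AUCs as `NaN` and are dropped
  from summaries; MCD failures fall back to the classical covariance;
  near-singular robust covariances are ridge-stabilized.
* The evaluation sizes used in the test suite (10 seeds, 5×2 and 2×2 CV,
  99 permutations, 200 calibration replicates) were chosen as the smallest
  designs whose conclusions were stable across reruns.

## Known limitations

Calendar-day windows, goalkeeper-specific handling, the REDI index,
hyperparameter search, conformal prediction and deep-learning ensembles are
out of scope. The column layouts of the variant tables follow the naming
scheme above rather than any particular published table layout; window sets
are configuration. Heatmap rendering (`renderFWFHeatmaps`) displays raw
cell values by default — normalization across events or variables is the
caller's choice before rendering.
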