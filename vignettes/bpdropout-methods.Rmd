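---
title: "Methods: modelling measurement continuity in home blood pressure monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling measurement continuity in home blood pressure monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Home blood pressure monitoring (HBPM) only helps patients who keep
measuring. Connected-device cohorts show high discontinuation, and an
intervention aimed at keeping patients engaged needs to know *who* is about
to stop *before* they stop. `bpdropout` implements a complete analysis of
measurement continuity for HBPM event streams: an operational definition of
dropout, leakage-safe predictive models of future dropout from short
measurement histories, additive attribution of those predictions to
interpretable features, and the descriptive epidemiology (non-resumption
curves, cumulative incidence, standardised cohort comparisons) that
validates the model's findings against the raw data.

Because real connected-device data are proprietary, the package ships a
synthetic cohort generator whose defaults encode the published marginals of
a large Japanese HBPM cohort. The generator is first-class, tested code: it
provides ground truth (true dropout days, per-covariate log-hazard
contributions) so that every downstream claim — "the model recovers the
planted U-shaped blood-pressure effect" — can be tested mechanically.

## Event definitions

* **Inactive (dropout)** at day $t$: no measurement in the trailing 28-day
  window $[t-27, t]$. The 28-day threshold is motivated by the observation
  that users with a 28-day gap rarely return: on default synthetic cohorts
  the non-resumption probability at a 28-day gap is about 85% (the
  acceptance script recomputes it), and `non_resumption_curve()` derives
  it from any event stream.
* **Resumption** after a gap: the earliest measurement day $r$ such that
  each of the four weeks $[r,r+6],\dots,[r+21,r+27]$ contains at least one
  measurement. A candidate too close to the data cutoff to confirm all four
  weeks is not a resumption; episodes with under 180 days of follow-up get
  an *undefined* (not false) resumption flag. The 180-day non-resumption
  clock starts at the first unmeasured day of the gap; starting it at the
  last measured day instead would shift every clock by one day and none of
  the package's conclusions.
* **Observation windows**: consecutive, non-overlapping 14-day segments
  anchored at each user's first measured day (not calendar-aligned — the
  event stream is personal, the calendar only matters through
  weekday/weekend structure). The trailing partial segment is discarded.
  Windows containing no measurements are retained by default, because
  days-since-last-measurement remains informative there; `drop_empty`
  switches this off.
* **Labels**: the classification target at horizon $X \in \{28, 35, \dots,
  91\}$ days is the inactive status evaluated pointwise at `end_day + X`
  with the trailing 28-day rule. The anchor makes $X=28$ read as "no
  measurement in the 28 days immediately after the window", the most
  natural interpretation. Labels whose evaluation day falls beyond the
  dataset cutoff are undefined and excluded per-horizon, never imputed.

## The synthetic behaviour process

Each user draws sex (male/female/unspecified at 61.4/29.1/9.5%), age
(normal 55.5 (SD 11.4) years, truncated to [18, 95]) and a long-run mean
systolic pressure (normal 128 (SD 12) mmHg). Daily behaviour is a two-state
process:

* **Active**: a measurement occurs each day with probability
  `plogis(qlogis(0.65) - 0.002 t)` — a slow logistic habit decay from
  initiation — multiplied by 0.85 on weekends. Measured days carry one
  reading (70%) or two (30%), echoing twice-daily measurement guidance.
  Readings are the user's mean plus daily noise (SD 7 mmHg); diastolic
  pressure is `0.6·SBP + N(0, 5)` and pulse `N(72, 8)`, plausibility
  relations only.
* **Dropout**: from the active state the user drops with per-day hazard
  $$h = h_0 \exp\!\big\{\beta_a ((a-60)/20)^2 + \beta_f 1[\text{female}]
  + \beta_u 1[\text{unspecified}] + \beta_s ((s^{max}-130)/20)^2 +
  1[B]\log m_B\big\}$$
  with $h_0 = 0.004$/day, $\beta_a = 0.5$, $\beta_f = 0.25$,
  $\beta_u = 0.45$, $\beta_s = 0.4$, $m_B = 1.3$. Age risk is U-shaped with
  its minimum at 60; the blood-pressure term is U-shaped in the user's
  *typical window-maximum* systolic reading $s^{max}$ (their mean plus 1.5
  daily SDs) with its minimum at 130 mmHg — the observable a dependence
  plot is read against is the window maximum, so the effect is planted on
  that scale. In the 28 days before the drawn dropout day,
  weekday measurement probability ramps linearly to zero: habit decline
  concentrates on working days, whose routine is the first casualty.
* **Dropped**: absorbing except for a 0.0015/day resumption probability,
  after which the active process restarts (the user may drop again; ground
  truth records the *first* dropout day).

Calendars are anchored at a fixed Monday so weekday effects reproduce
exactly; users enter uniformly over the first 28 days and are observed to
day 280. These sizes keep a 5000-user cohort — roughly 90,000 windows —
within a desk-scale compute budget while leaving every age/sex stratum
populated.

**What the generator does not emulate**: medication or treatment status,
clinic-visit schedules, device models, intra-day timing, seasonality,
calendar-time shifts in user demographics, and any dependence of
measurement *values* on engagement. Passing effect-recovery tests on this
cohort therefore demonstrates that the pipeline's machinery is correct and
sensitive, not that real HBPM data carry these effect sizes.

## Features

`feature_catalogue()` defines 37 features in three groups: measurement
pattern (counts, week-1/week-2 day counts and their all/weekday/weekend
deltas, within-window gaps and streaks, days since first/last measurement,
readings in the user's first fortnight), vital-sign summaries for
SBP/DBP/pulse (mean, SD, min, max, last-minus-first daily mean, OLS slope
of daily means on the day index), and demographics (age at window end from
the year-month birth field, plus two flags: `is_female` and
`sex_provided`, so that a three-level sex variable enters the model without
an artificial ordering). Windows with no readings have vital statistics
coded `NA` — never silently zero. The tree learner routes `NA` natively;
the logistic learner imputes training-column means, a documented choice
stored on the fitted object and reused at prediction time.

Two exact decompositions are maintained and tested: week-1 plus week-2
day counts equal the window's measured days, and the weekday plus weekend
deltas equal the whole-week delta.

## Models and validation

`fit_dropout_model()` trains either gradient-boosted trees (xgboost,
leaf-wise growth — the same model family as LightGBM, which R lacks a
binding for) or an L2-penalised logistic regression (glmnet). Validation is
leakage-safe at two levels:

* **Cohort split** (`split_cohorts()`): all regime-A users (the analogue of
  an era without push notifications) form Test 1; an equal-size random
  sample of regime-B users forms Test 2; remaining users train the model.
  Assignment is by user, never by window.
* **Grouped cross-validation**: five folds grouped by user, so no user's
  windows straddle a fold boundary. Whether real-data folds should be
  user-grouped is not documented anywhere authoritative; grouping is the
  defensible default because windows of one user are strongly dependent.

Hyperparameters are drawn by seeded random search (20–50 trials at full
scale; 4 in the shipped study-scale runs) over a fixed space: 15–255
leaves, learning rate 0.01–0.3 and minimum child weight 5–100 all
log-uniform, row/feature subsampling 0.5–1, up to 300 trees with early
stopping (patience 25) on fold-validation logloss; for the logistic model,
an L2 penalty log-uniform on $[10^{-4}, 10^2]$ over standardised inputs. A
Bayesian (TPE-style) sampler would need an optimisation dependency the
package deliberately avoids; at these budgets random search explores the
space without sampler bias and is exactly reproducible from one seed. Two
details matter:

* The **tuner selects trials by mean fold AUC** (the study's reported
  metric), but **early stopping watches logloss**. A rank metric saturates
  within a handful of trees once the dominant behavioural features are in,
  which freezes the ensemble before weak-but-real effects (the sex flags,
  the blood-pressure extremes) enter at all; logloss keeps improving as
  probabilities refine, which is also the default stopping metric of the
  reference gradient-boosting implementation for binary tasks.
* Class imbalance is left unweighted: AUC is the evaluation target and
  reweighting would change only the probability calibration, which the
  package does not claim.

AUC is computed as the tie-averaged rank statistic and is tested to equal
trapezoidal integration of the exported ROC points to $10^{-9}$; a
single-class evaluation set raises an error rather than returning NaN.

## Attributions

`compute_attributions()` produces additive per-row explanations in
log-odds units with the *local accuracy* guarantee `base + Σ attributions
= margin` to double precision. For trees this is path-dependent TreeSHAP,
implemented in C++ inside the package and evaluated in double precision
over the dumped ensemble; split comparisons are performed in float32 to
mirror the trainer's routing exactly, and the per-row margin is recomputed
in double from the leaf values. The upstream float32 implementation is
used as an independent cross-check in the test suite, not as the engine,
because its additivity error (about $2\times10^{-5}$ at realistic margins)
exceeds the package's $10^{-6}$ contract. For the logistic model the
attributions are the exact linear ones, $\beta_j (x_j - \bar x_j)$ with
training means as background.

Summary tooling mirrors standard interpretation practice:
`rank_features()` (mean absolute attribution, ties broken in catalogue
order), `dependence_profile()` (20 equal-count bins by default, optional
colour-by stratification), and `detect_ushape()`, which declares a U-shape
only when the mean attribution in both extreme regions exceeds the middle
band's mean by a stated margin, and returns *undefined* when an extreme
region is empty. The default bands for the window-maximum SBP test
(110 / [120, 135] / 150 mmHg) bracket the clinically salient thresholds: a
guideline home target near 135 mmHg and the sharp risk escalation above
150 mmHg. Attributions are evaluated on the Test-2-analogue users, the set
whose era matches the models' headline evaluation.

## Descriptive analyses

* `non_resumption_curve()`: among gap episodes reaching at least $d$
  unmeasured days (risk sets nest, so the curve is non-decreasing up to
  noise), the fraction never resuming within 180 days.
* `cumulative_incidence()`: complement of the product-limit (Kaplan–Meier)
  survival estimator via the survival package; "dropout" is the first
  onset of the inactive state (the 28th day of the first long gap), users
  never reaching it are censored at the cutoff.
* `standardized_incidence_comparison()`: direct standardisation of two
  cohorts' incidence curves over age-decade × sex strata, weighted by the
  pooled stratum distribution (the pooled reference avoids privileging
  either cohort); strata absent from either side are dropped from both
  with a warning.
* `monthly_dropout_rate()`: per calendar month, first onsets among users
  measured within the preceding 28 days of the month start.
* `compare_week_delta_by_outcome()`: two-sided Mann–Whitney rank-sum test
  comparing week-over-week measurement change between continuation and
  dropout groups, for the whole week, weekdays only, and weekends only.
* Age bins are decades 18–29 through 80+ throughout.

## Numerical and degenerate-input conventions

* Day granularity everywhere; multiple same-day readings collapse to one
  measured day for event logic but keep their count and values for
  features.
* Vital slopes are OLS on (day index, daily mean) pairs and undefined with
  fewer than two measured days; SDs undefined with fewer than two
  readings.
* Quantile bin edges are deduplicated; a constant feature yields one bin.
* Empty cohorts, empty windows, single-class labels, off-grid horizons,
  unparseable dates and non-positive vitals all follow the documented
  error or missing-value path; nothing is silently coerced.
* All randomness flows through explicit integer seeds: the generator, the
  split, fold assignment, the parameter sampler and xgboost itself.
  Refitting with the same seed reproduces hyperparameters exactly and tree
  predictions to float32 noise.

## Problem sizes

The shipped study-scale runs use a 5000-user default cohort (about 90,000
windows), horizons {28, 56, 84}, five grouped folds and four search trials;
the acceptance script uses 2000 users with the same grid. These sizes were
chosen so each planted effect is resolvable with comfortable margins while
a full run stays in the minutes range on a single core; the full 28–91
grid and 50-trial budgets are a configuration change, not a code change.

## Known limitations

* The generator's dropout hazard is constant over time within a user;
  real cohorts show calendar-time and duration effects the standardised
  comparison would pick up.
* Probability calibration of the classifiers is out of scope; predicted
  probabilities should be treated as scores.
* The non-resumption flag near the data cutoff is conservative: a genuine
  resumption whose 4-week confirmation window is truncated counts as not
  resumed.
* With heavily correlated features (window SBP mean, min and max), additive
  attributions spread credit across the correlated set; the U-shape test
  on the window maximum is therefore a weaker signal than the planted
  hazard coefficient alone would suggest, which is the realistic setting.
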