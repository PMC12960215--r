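# bpdropout

Dropout prediction and engagement analysis for home blood pressure
monitoring (HBPM).

Regular self-measurement of blood pressure is central to hypertension
management, yet connected-device cohorts lose most of their users within a
year. `bpdropout` is an R package for analysts of such measurement streams:
it operationalises *dropout* as 28 consecutive days without a measurement,
predicts that state 28–91 days ahead from a single 14-day window of
measurement patterns and demographics, explains the predictions with exact
additive (Shapley) feature attributions, and reproduces the descriptive
epidemiology — non-resumption curves, age-binned dropout rates,
sex-stratified cumulative incidence, age/sex-standardised cohort
comparisons, monthly rates — that grounds those predictions in the raw
data.

Because real device data are proprietary, the package includes a tested
synthetic cohort generator with published-marginal defaults (age 55.5 (SD
11.4) years; 61.4/29.1/9.5% male/female/unspecified; median user-mean SBP
≈ 128 mmHg) and a known dropout process, so every claim the pipeline makes
can be checked against planted ground truth.

## The model

For user *u* with first measurement on day 0, windows are the consecutive
14-day segments `[14k, 14k+13]`. From each window, 37 features are
computed (measurement counts and streaks, week-1/week-2 day counts and
their weekday/weekend deltas, days since first/last measurement, SBP/DBP/
pulse summaries including the window maximum and an OLS slope, age and two
sex flags). The label at horizon *X* is

> y_X = 1 iff no measurement falls in `[end + X − 27, end + X]`,

i.e. the user is inactive X days after the window ends. Classifiers —
gradient-boosted trees (xgboost) and L2-penalised logistic regression
(glmnet) — are tuned by seeded random search under fivefold
cross-validation grouped by user, and evaluated on held-out user cohorts
split by regime (an all-regime-A "Test 1" and a size-matched regime-B
"Test 2"), so no user's windows ever leak across a split. ROC-AUC is the
tie-averaged rank statistic, identical to trapezoidal integration of the
ROC points. Attributions satisfy local accuracy
`base + Σ φ_j = log-odds margin` to double precision (path-dependent
TreeSHAP implemented in C++ for the trees; exact linear attributions for
the logistic model).

In the synthetic generator, the per-day dropout hazard is

    h = h0 · exp{ βa·((age−60)/20)² + βf·1[female] + βu·1[unspecified]
                  + βs·((s_max−130)/20)² + 1[regime B]·log m_B }

with U-shaped age and blood-pressure terms (s_max is the user's typical
window-maximum SBP), and weekday measurement probability ramps to zero over
the four weeks before dropout — the structures the interpretation tooling
is expected to recover.

## Worked example

```r
library(bpdropout)

cfg     <- cohort_config(n_users = 800, seed = 42)
cohort  <- simulate_cohort(cfg)
cohort
#> Synthetic HBPM cohort: 800 users, 69289 readings over 280 days
#>   users with a true dropout day: 688 (86.0%)

series   <- build_daily_series(cohort$measurements,
                               cutoff_day = cfg$calendar_span_days - 1L)
windows  <- label_windows(series, x_grid = c(28L, 56L))
features <- build_feature_matrix(series, windows, cohort$users)
split    <- split_cohorts(cohort$users, seed = 1)
split
#> split_plan: 472 train / 164 test1 (regime A) / 164 test2 (regime B), seed 1

ok  <- !is.na(windows$y_56) & windows$user_id %in% split$train
fit <- fit_dropout_model(features[ok, ], windows$y_56[ok],
                         windows$user_id[ok], model_type = "gbt",
                         budget_trials = 4, seed = 1)
fit
#> Dropout classifier (gbt): 37 features, 6623 training rows
#>   grouped 5-fold CV AUC 0.9078 (sd 0.0085), 4 search trials

test2 <- !is.na(windows$y_56) & windows$user_id %in% split$test2
evaluate_auc(fit, features[test2, ], windows$y_56[test2])
#> AUC 0.9120 on 2257 rows (1219 positive)
```

A cross-validated AUC of 0.91 at the 56-day horizon means the model ranks
a randomly chosen future dropout above a randomly chosen continuer 91% of
the time, using nothing but one 14-day window. Attribution shows *why*:

```r
shap <- compute_attributions(fit, features[test2, ])
head(rank_features(shap), 5)
#>   rank              feature mean_abs_attribution
#> 1    1         n_days_week2            0.6736429
#> 2    2 days_since_last_meas            0.4268119
#> 3    3      n_days_measured            0.4140684
#> 4    4         n_meas_total            0.2015368
#> 5    5            age_years            0.1684744
```

Recent measurement frequency dominates, with demographics next — the
pattern the planted hazard dictates. The descriptive side closes the loop;
here, 86% of users whose gap reached 28 days never resumed within 180
days, which is what motivates the 28-day inactivity definition:

```r
gaps <- do.call(rbind, lapply(series, detect_gaps))
non_resumption_curve(gaps, d_grid = c(7, 14, 28))
#>    d n_at_risk n_not_resumed     value
#> 1  7       500           386 0.7720000
#> 2 14       393           328 0.8346056
#> 3 28       381           327 0.8582677
```

`run_pipeline(pipeline_config(...), out_dir)` executes the whole chain —
simulate, label, featurize, train across horizons, attribute, describe —
and writes every artifact (CSV/JSON plus a manifest with config hash and
seeds) reproducibly.

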