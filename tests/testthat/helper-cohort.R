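# Shared study-scale fixture, built on first use and memoised for the
# session. All downstream stages derive from one default cohort of 5000
# users so the training-dependent checks exercise the same conditions.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

study_cohort <- function() memo("cohort", function() {
  simulate_cohort(cohort_config(n_users = 5000L, seed = 7L))
})

study_series <- function() memo("series", function() {
  cfg <- study_cohort()$config
  build_daily_series(study_cohort()$measurements,
                     cutoff_day = cfg$calendar_span_days - 1L)
})

study_windows <- function() memo("windows", function() {
  label_windows(study_series(), x_grid = c(28L, 56L, 84L))
})

study_features <- function() memo("features", function() {
  build_feature_matrix(study_series(), study_windows(),
                       study_cohort()$users)
})

study_split <- function() memo("split", function() {
  split_cohorts(study_cohort()$users, seed = 11L)
})

study_sweep <- function() memo("sweep", function() {
  horizon_sweep(study_features(), study_windows(), study_split(),
                x_grid = c(28L, 56L, 84L), budget_trials = 4L, seed = 11L)
})

# attribution report for the 56-day tree model on the regime-B test users
study_shap <- function() memo("shap", function() {
  lw <- study_windows()
  rows <- lw$user_id %in% study_split()$test2 & !is.na(lw$y_56)
  compute_attributions(study_sweep()$models[["gbt_56"]],
                       study_features()[rows, , drop = FALSE])
})

# small cohort for the feature-invariant suite
feature_cohort <- function() memo("feature_cohort", function() {
  coh <- simulate_cohort(cohort_config(n_users = 2000L, seed = 13L))
  series <- build_daily_series(coh$measurements,
                               cutoff_day = coh$config$calendar_span_days - 1L)
  lw <- label_windows(series, x_grid = 56L)
  list(cohort = coh, series = series, windows = lw,
       features = build_feature_matrix(series, lw, coh$users))
})
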