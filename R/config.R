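#' Configuration for the synthetic measurement cohort generator
#'
#' Builds and validates the parameter set that [simulate_cohort()] uses to
#' generate a home blood pressure monitoring cohort. Defaults reproduce the
#' demographic marginals of a large Japanese connected-device cohort
#' (age 55.5 (SD 11.4) years; 61.4/29.1/9.5% male/female/unspecified;
#' median user-mean systolic pressure about 128 mmHg) together with an
#' engagement process in which daily measurement is a Bernoulli event whose
#' probability decays slowly from initiation, dropout is an absorbing state
#' entered with a covariate-dependent per-day hazard, and resumption is rare.
#'
#' The per-day dropout hazard for a user is
#' \deqn{h = h_0 \exp\{\beta_{age} ((a-60)/20)^2 + \beta_f 1[female] +
#'   \beta_u 1[unspecified] + \beta_s ((s^{max}-130)/20)^2 + 1[B]\log m_B\}}
#' where \eqn{a} is age in years, \eqn{s^{max}} the user's typical maximum
#' systolic reading over a 2-week window (their long-run mean plus 1.5
#' within-user daily SDs, mmHg), and \eqn{m_B} the regime-B hazard
#' multiplier. Both quadratic terms are U-shaped: risk is lowest near age
#' 60 and near a 130 mmHg window maximum and rises toward both extremes. In the `weekday_decline_days`
#' before the dropout day, weekday measurement probability ramps linearly
#' to zero, emulating habit decay concentrated on working days.
#'
#' @param n_users Number of users to simulate.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param calendar_span_days Length of the observation calendar in days.
#' @param entry_window_days Users enter uniformly over the first this-many
#'   days of the calendar (0 = everyone starts on day 0, a Monday).
#' @param sex_probs Probabilities of male, female, unspecified sex; must sum
#'   to 1.
#' @param age_mean_sd Mean and SD of age (years) at entry.
#' @param age_bounds Truncation bounds for age (years).
#' @param sbp_user_mean_sd Mean and SD across users of the long-run mean
#'   systolic blood pressure (mmHg).
#' @param sbp_daily_sd Within-user day-to-day SD of systolic readings (mmHg).
#' @param base_daily_meas_prob Probability of measuring on a weekday at
#'   entry, before habit decay.
#' @param habit_decay_rate Per-day decline of the measurement log-odds.
#' @param weekend_meas_multiplier Multiplier applied to the measurement
#'   probability on Saturdays and Sundays.
#' @param prob_second_reading Probability that a measured day carries two
#'   readings rather than one.
#' @param baseline_hazard Per-day dropout hazard at the covariate reference
#'   (age 60, male, mean SBP 130 mmHg, regime A).
#' @param effect_age_quadratic Log-hazard coefficient on `((age-60)/20)^2`.
#' @param effect_female Log-hazard increment for female users.
#' @param effect_unspecified Log-hazard increment for users who did not
#'   provide sex information.
#' @param effect_sbp_ushape Log-hazard coefficient on `((sbp-130)/20)^2`.
#' @param weekday_decline_days Days before dropout over which weekday
#'   measurement probability ramps linearly to 0.
#' @param resumption_prob Per-day probability of leaving the dropped state.
#' @param regime_B_fraction Probability that a user belongs to regime B
#'   (the analogue of the period with push notifications).
#' @param regime_B_hazard_multiplier Hazard ratio of regime B vs regime A.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @examples
#' cfg <- cohort_config(n_users = 100, seed = 1)
#' cfg$sex_probs
#' @export
cohort_config <- function(n_users = 1000L,
                          seed = 1L,
                          calendar_span_days = 280L,
                          entry_window_days = 28L,
                          sex_probs = c(male = 0.614, female = 0.291, unspecified = 0.095),
                          age_mean_sd = c(55.5, 11.4),
                          age_bounds = c(18, 95),
                          sbp_user_mean_sd = c(128, 12),
                          sbp_daily_sd = 7,
                          base_daily_meas_prob = 0.65,
                          habit_decay_rate = 0.002,
                          weekend_meas_multiplier = 0.85,
                          prob_second_reading = 0.3,
                          baseline_hazard = 0.004,
                          effect_age_quadratic = 0.5,
                          effect_female = 0.25,
                          effect_unspecified = 0.45,
                          effect_sbp_ushape = 0.4,
                          weekday_decline_days = 28L,
                          resumption_prob = 0.0015,
                          regime_B_fraction = 0.8,
                          regime_B_hazard_multiplier = 1.3) {
  cfg <- list(
    n_users = as.integer(n_users), seed = as.integer(seed),
    calendar_span_days = as.integer(calendar_span_days),
    entry_window_days = as.integer(entry_window_days),
    sex_probs = sex_probs, age_mean_sd = age_mean_sd, age_bounds = age_bounds,
    sbp_user_mean_sd = sbp_user_mean_sd, sbp_daily_sd = sbp_daily_sd,
    base_daily_meas_prob = base_daily_meas_prob,
    habit_decay_rate = habit_decay_rate,
    weekend_meas_multiplier = weekend_meas_multiplier,
    prob_second_reading = prob_second_reading,
    baseline_hazard = baseline_hazard,
    effect_age_quadratic = effect_age_quadratic,
    effect_female = effect_female,
    effect_unspecified = effect_unspecified,
    effect_sbp_ushape = effect_sbp_ushape,
    weekday_decline_days = as.integer(weekday_decline_days),
    resumption_prob = resumption_prob,
    regime_B_fraction = regime_B_fraction,
    regime_B_hazard_multiplier = regime_B_hazard_multiplier
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stop_if_not(cfg$n_users >= 0L, "n_users must be non-negative")
  stop_if_not(cfg$calendar_span_days >= 1L, "calendar_span_days must be positive")
  stop_if_not(cfg$entry_window_days >= 0L &&
                cfg$entry_window_days < cfg$calendar_span_days,
              "entry_window_days must lie in [0, calendar_span_days)")
  stop_if_not(length(cfg$sex_probs) == 3L && all(cfg$sex_probs >= 0),
              "sex_probs must be three non-negative probabilities")
  stop_if_not(abs(sum(cfg$sex_probs) - 1) <= 1e-12,
              "sex_probs must sum to 1")
  probs <- c(cfg$base_daily_meas_prob, cfg$prob_second_reading,
             cfg$resumption_prob, cfg$regime_B_fraction)
  stop_if_not(all(probs >= 0 & probs <= 1),
              "probabilities must lie in [0, 1]")
  stop_if_not(cfg$baseline_hazard >= 0 && cfg$baseline_hazard <= 1,
              "baseline_hazard must lie in [0, 1]")
  nonneg <- c(cfg$age_mean_sd[2], cfg$sbp_user_mean_sd[2], cfg$sbp_daily_sd,
              cfg$habit_decay_rate, cfg$weekday_decline_days,
              cfg$regime_B_hazard_multiplier, cfg$weekend_meas_multiplier)
  stop_if_not(all(nonneg >= 0), "rates, SDs and multipliers must be >= 0")
  stop_if_not(cfg$age_bounds[1] < cfg$age_bounds[2], "age_bounds must increase")
  invisible(cfg)
}

#' @method print cohort_config
#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic HBPM cohort configuration\n")
  cat(sprintf("  users: %d   calendar span: %d days   seed: %d\n",
              x$n_users, x$calendar_span_days, x$seed))
  cat(sprintf("  sex probs (M/F/unspec): %.3f/%.3f/%.3f   age: %.1f (%.1f)\n",
              x$sex_probs[1], x$sex_probs[2], x$sex_probs[3],
              x$age_mean_sd[1], x$age_mean_sd[2]))
  cat(sprintf("  baseline hazard: %.4g/day   resumption: %.4g/day\n",
              x$baseline_hazard, x$resumption_prob))
  invisible(x)
}

#' End-to-end pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]. Defaults encode
#' the analysis constants: 28-day inactivity threshold, 14-day observation
#' windows, prediction horizons 28 to 91 days in 7-day steps, fivefold
#' user-grouped cross-validation.
#'
#' @param generator A [cohort_config()].
#' @param inactivity_threshold Days without measurement that define the
#'   inactive state.
#' @param window_len Observation window length in days.
#' @param x_grid Prediction horizons (days after window end).
#' @param drop_empty_windows Drop windows containing no measurements?
#' @param model_types Learners to train, subset of `c("gbt", "logistic")`.
#' @param n_folds Cross-validation folds.
#' @param budget_trials Hyperparameter search trials per model.
#' @param shap_horizon Horizon whose model is interpreted.
#' @param seed Seed for splitting/training randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(),
                            inactivity_threshold = 28L,
                            window_len = 14L,
                            x_grid = seq(28L, 91L, by = 7L),
                            drop_empty_windows = FALSE,
                            model_types = c("gbt", "logistic"),
                            n_folds = 5L,
                            budget_trials = 50L,
                            shap_horizon = 56L,
                            seed = 1L) {
  stop_if_not(inherits(generator, "cohort_config"),
              "generator must be a cohort_config")
  stop_if_not(all(x_grid %in% seq(28L, 91L, by = 7L)),
              "x_grid must lie on the 7-day grid 28..91")
  stop_if_not(shap_horizon %in% x_grid, "shap_horizon must be in x_grid")
  structure(list(
    generator = generator,
    inactivity_threshold = as.integer(inactivity_threshold),
    window_len = as.integer(window_len),
    x_grid = as.integer(x_grid),
    drop_empty_windows = isTRUE(drop_empty_windows),
    model_types = match.arg(model_types, c("gbt", "logistic"), several.ok = TRUE),
    n_folds = as.integer(n_folds),
    budget_trials = as.integer(budget_trials),
    shap_horizon = as.integer(shap_horizon),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}
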