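#' Simulate a home blood pressure monitoring cohort
#'
#' Generates per-user profiles, per-reading measurement records and the
#' ground-truth dropout process under the behaviour model described in
#' [cohort_config()]: a two-state (active/dropped) process in which an
#' active user measures each day with a probability that decays from
#' initiation and is lower on weekends; dropout day is drawn from a
#' geometric distribution with a covariate-dependent per-day hazard
#' (U-shaped in age and in user-mean systolic pressure, elevated for female
#' and sex-unspecified users and under regime B); the dropped state is
#' absorbing except for a small per-day resumption probability. In the
#' `weekday_decline_days` preceding dropout, weekday measurement probability
#' ramps linearly to zero. Diastolic pressure is generated as
#' `0.6 * SBP + N(0, 5)` and pulse as `N(72, 8)`; these relations are
#' plausibility choices, not estimates.
#'
#' @param config A [cohort_config()].
#' @return A list of class `bp_cohort` with elements
#'   \describe{
#'     \item{users}{data.frame: `user_id`, `birth_ym` ("YYYY-MM"), `sex`
#'       (male/female/unspecified), `regime` (A/B).}
#'     \item{measurements}{data.frame: `user_id`, `date` (Date), `sbp`,
#'       `dbp`, `pulse`; one row per reading.}
#'     \item{truth}{data.frame: per user `true_dropout_day` (day index of
#'       first entry into the dropped state, NA if never), the log-hazard
#'       contribution of each covariate (`lh_age`, `lh_female`,
#'       `lh_unspecified`, `lh_sbp`, `lh_regime`), the per-day `hazard`,
#'       `entry_day`, `age_years`, `sbp_user_mean` and `regime`.}
#'   }
#'   The result is a deterministic function of `config` (including its seed).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_users = 20, seed = 42))
#' head(coh$measurements)
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_users
  span <- config$calendar_span_days
  if (n == 0L) {
    return(structure(list(users = empty_users(), measurements = empty_measurements(),
                          truth = empty_truth(), config = config),
                     class = "bp_cohort"))
  }

  set.seed(config$seed)
  user_id <- sprintf("u%05d", seq_len(n))
  sex <- sample(c("male", "female", "unspecified"), n, replace = TRUE,
                prob = config$sex_probs)
  age <- rnorm(n, config$age_mean_sd[1], config$age_mean_sd[2])
  age <- pmin(pmax(age, config$age_bounds[1]), config$age_bounds[2])
  sbp_mean <- rnorm(n, config$sbp_user_mean_sd[1], config$sbp_user_mean_sd[2])
  regime <- ifelse(runif(n) < config$regime_B_fraction, "B", "A")
  entry_day <- if (config$entry_window_days > 0L) {
    sample.int(config$entry_window_days, n, replace = TRUE) - 1L
  } else rep(0L, n)

  lh_age <- config$effect_age_quadratic * ((age - 60) / 20)^2
  lh_female <- ifelse(sex == "female", config$effect_female, 0)
  lh_unspecified <- ifelse(sex == "unspecified", config$effect_unspecified, 0)
  # The SBP risk term is U-shaped in the user's typical *maximum* reading
  # over an observation window (approximately mean + 1.5 daily SDs), with
  # its minimum at 130 mmHg on that scale: extreme maxima in either
  # direction raise the dropout hazard.
  sbp_typical_max <- sbp_mean + 1.5 * config$sbp_daily_sd
  lh_sbp <- config$effect_sbp_ushape * ((sbp_typical_max - 130) / 20)^2
  lh_regime <- ifelse(regime == "B", log(config$regime_B_hazard_multiplier), 0)
  hazard <- pmin(config$baseline_hazard *
                   exp(lh_age + lh_female + lh_unspecified + lh_sbp + lh_regime),
                 0.5)

  # birth month consistent with age at entry
  birth_date <- day_to_date(entry_day) - round(age * 365.25)
  birth_ym <- format(birth_date, "%Y-%m")

  base_logit <- qlogis(config$base_daily_meas_prob)

  meas_user <- vector("list", n)
  meas_day <- vector("list", n)
  meas_cnt <- vector("list", n)
  true_dropout_day <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    followup <- span - entry_day[i]
    rel <- 0L
    first_drop <- NA_integer_
    days_i <- integer(0)
    while (rel < followup) {
      # active episode: draw time-to-dropout from the geometric hazard
      d <- if (hazard[i] > 0) rgeom(1L, hazard[i]) else NA_integer_
      drop_rel <- if (is.na(d)) NA_integer_ else rel + d
      ep_end <- if (is.na(drop_rel)) followup else min(drop_rel, followup)
      if (ep_end > rel) {
        t <- rel:(ep_end - 1L)
        abs_day <- entry_day[i] + t
        p <- plogis(base_logit - config$habit_decay_rate * t)
        wknd <- is_weekend(abs_day)
        p[wknd] <- p[wknd] * config$weekend_meas_multiplier
        if (!is.na(drop_rel) && drop_rel < followup &&
            config$weekday_decline_days > 0L) {
          ramp_idx <- !wknd & t >= drop_rel - config$weekday_decline_days
          p[ramp_idx] <- p[ramp_idx] *
            (drop_rel - t[ramp_idx]) / config$weekday_decline_days
        }
        measured <- runif(length(t)) < p
        days_i <- c(days_i, abs_day[measured])
      }
      if (is.na(drop_rel) || drop_rel >= followup) break
      if (is.na(first_drop)) first_drop <- entry_day[i] + drop_rel
      # dropped state: wait for a resumption event
      if (config$resumption_prob <= 0) break
      w <- rgeom(1L, config$resumption_prob)
      rel <- drop_rel + 1L + w
    }
    true_dropout_day[i] <- first_drop
    if (length(days_i)) {
      cnt <- 1L + (runif(length(days_i)) < config$prob_second_reading)
      meas_user[[i]] <- rep(user_id[i], sum(cnt))
      meas_day[[i]] <- rep(days_i, cnt)
      meas_cnt[[i]] <- cnt
    }
  }

  all_day <- unlist(meas_day)
  n_read <- length(all_day)
  if (n_read) {
    sbp_user <- rep(sbp_mean, vapply(meas_day, length, 0L))
    sbp <- round(sbp_user + rnorm(n_read, 0, config$sbp_daily_sd))
    dbp <- round(0.6 * sbp + rnorm(n_read, 0, 5))
    pulse <- round(rnorm(n_read, 72, 8))
    measurements <- data.frame(
      user_id = unlist(meas_user),
      date = day_to_date(all_day),
      sbp = sbp, dbp = pmax(dbp, 30), pulse = pmax(pulse, 30),
      stringsAsFactors = FALSE
    )
  } else {
    measurements <- empty_measurements()
  }

  users <- data.frame(user_id = user_id, birth_ym = birth_ym, sex = sex,
                      regime = regime, stringsAsFactors = FALSE)
  truth <- data.frame(
    user_id = user_id, true_dropout_day = true_dropout_day,
    lh_age = lh_age, lh_female = lh_female, lh_unspecified = lh_unspecified,
    lh_sbp = lh_sbp, lh_regime = lh_regime, hazard = hazard,
    entry_day = entry_day, age_years = age, sbp_user_mean = sbp_mean,
    regime = regime, stringsAsFactors = FALSE
  )
  structure(list(users = users, measurements = measurements, truth = truth,
                 config = config),
            class = "bp_cohort")
}

empty_users <- function() {
  data.frame(user_id = character(0), birth_ym = character(0),
             sex = character(0), regime = character(0),
             stringsAsFactors = FALSE)
}

empty_measurements <- function() {
  data.frame(user_id = character(0), date = as.Date(character(0)),
             sbp = numeric(0), dbp = numeric(0), pulse = numeric(0),
             stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(user_id = character(0), true_dropout_day = integer(0),
             lh_age = numeric(0), lh_female = numeric(0),
             lh_unspecified = numeric(0), lh_sbp = numeric(0),
             lh_regime = numeric(0), hazard = numeric(0),
             entry_day = integer(0), age_years = numeric(0),
             sbp_user_mean = numeric(0), regime = character(0),
             stringsAsFactors = FALSE)
}

#' @method print bp_cohort
#' @export
print.bp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic HBPM cohort: %d users, %d readings over %d days\n",
              nrow(x$users), nrow(x$measurements),
              x$config$calendar_span_days))
  if (nrow(x$truth)) {
    cat(sprintf("  users with a true dropout day: %d (%.1f%%)\n",
                sum(!is.na(x$truth$true_dropout_day)),
                100 * mean(!is.na(x$truth$true_dropout_day))))
  }
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Writes `users.csv`, `measurements.csv` and `truth.csv` under `dir`.
#' Dates are written as ISO-8601 days; the files round-trip through
#' [read_users()], [read_measurements()] and [read_truth()].
#'
#' @param cohort A `bp_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (named character vector).
#' @export
write_cohort <- function(cohort, dir) {
  stop_if_not(inherits(cohort, "bp_cohort"), "cohort must be a bp_cohort")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(users = file.path(dir, "users.csv"),
             measurements = file.path(dir, "measurements.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(cohort$users, paths[["users"]], row.names = FALSE)
  m <- cohort$measurements
  m$date <- format(m$date, "%Y-%m-%d")
  utils::write.csv(m, paths[["measurements"]], row.names = FALSE)
  export_truth(cohort$truth, paths[["truth"]])
  invisible(paths)
}

#' Export and re-import the ground-truth table
#'
#' The ground truth (true dropout day and per-covariate log-hazard
#' contributions) supports effect-recovery tests; it is written as plain
#' CSV and round-trips losslessly.
#'
#' @param truth The `truth` data.frame of a `bp_cohort`.
#' @param path Output CSV path.
#' @return `export_truth` invisibly returns `path`; `read_truth` returns the
#'   data.frame with column types restored.
#' @export
export_truth <- function(truth, path) {
  stop_if_not(is.data.frame(truth), "truth must be a data.frame")
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(user_id = "character"))
  if (nrow(df) == 0L) return(empty_truth())
  df$true_dropout_day <- as.integer(df$true_dropout_day)
  df$entry_day <- as.integer(df$entry_day)
  df
}
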