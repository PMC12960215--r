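#' Catalogue of window features
#'
#' Stable, ordered schema of the measurement-pattern, vital-sign and
#' demographic features computed per 14-day observation window. Vital
#' statistics are `NA`-coded when the window holds no readings (never
#' silently zero); the two sex flags (`is_female`, `sex_provided`) encode a
#' three-level sex variable without imposing an order.
#'
#' @return data.frame with columns `name`, `formula_id`, `group`
#'   (`pattern` / `vitals` / `demographic`), in the order used by
#'   [extract_features()] and [build_feature_matrix()].
#' @export
feature_catalogue <- function() {
  pat <- c(
    n_meas_total = "count of readings in window",
    n_days_measured = "days with >=1 reading",
    days_since_last_meas = "window end - last measured day <= end",
    days_since_first_meas = "window end - user first measured day",
    n_meas_first14 = "readings in user's first 14 days",
    daily_count_mean = "mean readings/day over the 14 days",
    daily_count_sd = "sd of readings/day over the 14 days",
    daily_count_max = "max readings in one day",
    n_days_week1 = "measured days in window days 1-7",
    n_days_week2 = "measured days in window days 8-14",
    delta_days_all = "week2 - week1 measured days",
    delta_days_weekday = "week2 - week1 measured days, Mon-Fri",
    delta_days_weekend = "week2 - week1 measured days, Sat-Sun",
    max_gap_in_window = "longest unmeasured run in window",
    longest_streak = "longest measured run in window",
    meas_per_measured_day = "readings per measured day"
  )
  vit <- unlist(lapply(c("sbp", "dbp", "pulse"), function(v) {
    x <- c("mean over readings", "sd over readings", "min over readings",
           "max over readings", "last-day mean minus first-day mean",
           "OLS slope of daily mean on day index")
    names(x) <- paste0(v, c("_mean", "_sd", "_min", "_max",
                            "_last_minus_first", "_slope_per_day"))
    x
  }))
  dem <- c(age_years = "age at window end from birth year-month",
           is_female = "1 if reported female",
           sex_provided = "1 if sex reported")
  data.frame(
    name = c(names(pat), names(vit), names(dem)),
    formula_id = unname(c(pat, vit, dem)),
    group = c(rep("pattern", length(pat)), rep("vitals", length(vit)),
              rep("demographic", length(dem))),
    stringsAsFactors = FALSE
  )
}

#' Extract the feature vector of one observation window
#'
#' Computes every catalogue feature for a single (user, window) pair.
#' Deterministic and invariant to the order of input records; week 1 is
#' window days 1–7, week 2 days 8–14, and weekday/weekend is taken from the
#' fixed Monday-anchored calendar (see [bp_origin()]).
#'
#' @param series A `daily_series` for the user.
#' @param window One row of [segment_windows()] output (or any list with
#'   `start_day`, `end_day`); must belong to the same user.
#' @param profile A list or one-row data.frame with `sex` and `birth_ym`.
#' @return Named numeric vector in catalogue order; vital statistics are
#'   `NA` when undefined.
#' @export
extract_features <- function(series, window, profile) {
  stop_if_not(inherits(series, "daily_series"), "series must be a daily_series")
  if (!is.null(window$user_id))
    stop_if_not(identical(window$user_id, series$user_id),
                "window/user mismatch")
  start <- as.integer(window$start_day); end <- as.integer(window$end_day)
  stop_if_not(end - start + 1L == 14L, "window must span exactly 14 days")

  d <- series$days
  j1 <- findInterval(start - 1L, d) + 1L
  j2 <- findInterval(end, d)
  wdays <- if (j2 >= j1) d[j1:j2] else integer(0)
  wcounts <- if (j2 >= j1) series$counts[j1:j2] else integer(0)

  rday <- series$readings$day
  i1 <- findInterval(start - 1L, rday) + 1L
  i2 <- findInterval(end, rday)
  rw <- if (i2 >= i1) series$readings[i1:i2, , drop = FALSE] else
    series$readings[0, , drop = FALSE]

  n_meas_total <- nrow(rw)
  n_days <- length(wdays)

  last_idx <- findInterval(end, d)
  dsl <- if (last_idx >= 1L) end - d[last_idx] else end - series$first_day

  f14 <- n_measured_readings(series, series$first_day, series$first_day + 13L)

  cnt14 <- integer(14L)
  if (n_days) cnt14[wdays - start + 1L] <- wcounts
  present <- cnt14 > 0L
  wd <- day_of_week(start + 0:13)
  wkend <- wd >= 5L
  wk1 <- 1:7; wk2 <- 8:14

  rle_p <- rle(present)
  max_gap <- if (any(!rle_p$values)) max(rle_p$lengths[!rle_p$values]) else 0L
  streak <- if (any(rle_p$values)) max(rle_p$lengths[rle_p$values]) else 0L

  out <- c(
    n_meas_total = n_meas_total,
    n_days_measured = n_days,
    days_since_last_meas = dsl,
    days_since_first_meas = end - series$first_day,
    n_meas_first14 = f14,
    daily_count_mean = mean(cnt14),
    daily_count_sd = stats::sd(cnt14),
    daily_count_max = max(cnt14),
    n_days_week1 = sum(present[wk1]),
    n_days_week2 = sum(present[wk2]),
    delta_days_all = sum(present[wk2]) - sum(present[wk1]),
    delta_days_weekday = sum(present[wk2] & !wkend[wk2]) -
      sum(present[wk1] & !wkend[wk1]),
    delta_days_weekend = sum(present[wk2] & wkend[wk2]) -
      sum(present[wk1] & wkend[wk1]),
    max_gap_in_window = max_gap,
    longest_streak = streak,
    meas_per_measured_day = if (n_days) n_meas_total / n_days else NA_real_
  )
  for (v in c("sbp", "dbp", "pulse")) {
    out <- c(out, vital_stats(rw, v, wdays, start))
  }
  sex <- as.character(profile$sex)
  out <- c(out,
           age_years = age_at_day(as.character(profile$birth_ym), end),
           is_female = as.numeric(sex == "female"),
           sex_provided = as.numeric(sex != "unspecified"))
  out
}

# summary statistics of one vital over the window's readings
vital_stats <- function(rw, v, wdays, start) {
  x <- rw[[v]]
  n <- length(x)
  if (n == 0L) {
    out <- rep(NA_real_, 6L)
  } else {
    dmean <- vapply(split(x, rw$day), mean, 0)
    k <- length(dmean)
    slope <- if (k >= 2L) {
      t <- wdays - start + 1
      stats::cov(t, dmean) / stats::var(t)
    } else NA_real_
    out <- c(mean(x), if (n >= 2L) stats::sd(x) else NA_real_,
             min(x), max(x), dmean[k] - dmean[1], slope)
  }
  names(out) <- paste0(v, c("_mean", "_sd", "_min", "_max",
                            "_last_minus_first", "_slope_per_day"))
  out
}

n_measured_readings <- function(series, from, to) {
  rday <- series$readings$day
  findInterval(to, rday) - findInterval(from - 1L, rday)
}

#' Build the full feature matrix of a cohort
#'
#' One row per (user, window), columns in catalogue order, aligned with the
#' window table produced by [label_windows()].
#'
#' @param series_list List of `daily_series`.
#' @param windows Window (or labeled-window) data.frame with `user_id`,
#'   `start_day`, `end_day`.
#' @param users User profile data.frame (`user_id`, `birth_ym`, `sex`).
#' @return data.frame with `user_id`, `start_day`, `end_day` and one column
#'   per catalogue feature.
#' @export
build_feature_matrix <- function(series_list, windows, users) {
  stop_if_not(all(windows$user_id %in% names(series_list)),
              "every window's user must have a daily_series")
  stop_if_not(all(windows$user_id %in% users$user_id),
              "every window's user must have a profile")
  prof <- users[match(windows$user_id, users$user_id), , drop = FALSE]
  feats <- matrix(NA_real_, nrow(windows), nrow(feature_catalogue()))
  for (i in seq_len(nrow(windows))) {
    feats[i, ] <- extract_features(
      series_list[[windows$user_id[i]]],
      list(user_id = windows$user_id[i],
           start_day = windows$start_day[i], end_day = windows$end_day[i]),
      list(sex = prof$sex[i], birth_ym = prof$birth_ym[i]))
  }
  colnames(feats) <- feature_catalogue()$name
  cbind(windows[, c("user_id", "start_day", "end_day")],
        as.data.frame(feats))
}
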