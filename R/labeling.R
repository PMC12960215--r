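#' Inactivity test at a given day
#'
#' A user is inactive at day `t` when no measurement occurred in the closed
#' interval `[t - threshold + 1, t]` — with the default threshold, the 28
#' days ending at `t`. This is the trailing-window operationalisation of the
#' "no measurements for 4 weeks" dropout definition.
#'
#' @param series A `daily_series`.
#' @param t Day index to evaluate.
#' @param threshold Length of the trailing window in days (default 28).
#' @return `TRUE`/`FALSE`. Requesting `t > cutoff_day` is an error
#'   (insufficient follow-up).
#' @export
inactive_at <- function(series, t, threshold = 28L) {
  stop_if_not(inherits(series, "daily_series"), "series must be a daily_series")
  stop_if_not(t <= series$cutoff_day,
              "insufficient follow-up: t exceeds cutoff_day")
  n_measured_in(series, t - threshold + 1L, t) == 0L
}

#' Segment a user's series into non-overlapping 14-day windows
#'
#' Consecutive windows are anchored at the user's first measured day; the
#' trailing partial segment (shorter than `window_len` before the cutoff) is
#' discarded. Windows containing no measurements are retained by default
#' (days-since-last-measurement remains informative there); set
#' `drop_empty = TRUE` to discard them.
#'
#' @param series A `daily_series`.
#' @param window_len Window length in days (default 14).
#' @param drop_empty Drop windows with no measured days?
#' @return data.frame with columns `user_id`, `start_day`, `end_day`
#'   (`end_day = start_day + window_len - 1`), oldest first.
#' @export
segment_windows <- function(series, window_len = 14L, drop_empty = FALSE) {
  stop_if_not(inherits(series, "daily_series"), "series must be a daily_series")
  span <- series$cutoff_day - series$first_day + 1L
  k <- span %/% window_len
  if (k == 0L) {
    return(data.frame(user_id = character(0), start_day = integer(0),
                      end_day = integer(0), stringsAsFactors = FALSE))
  }
  start <- series$first_day + window_len * (seq_len(k) - 1L)
  out <- data.frame(user_id = rep(series$user_id, k), start_day = start,
                    end_day = start + window_len - 1L,
                    stringsAsFactors = FALSE)
  if (drop_empty) {
    keep <- vapply(seq_len(k), function(i)
      n_measured_in(series, out$start_day[i], out$end_day[i]) > 0L, TRUE)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Horizon label for one observation window
#'
#' The classification target at horizon `X` is the inactive status evaluated
#' `X` days after the window end: `inactive_at(series, end_day + X)`. The
#' label is undefined (`NA`) when `end_day + X` exceeds the dataset cutoff.
#'
#' @param series A `daily_series`.
#' @param end_day Window end day.
#' @param X Horizon in days; must lie on the 7-day grid 28..91.
#' @param threshold Inactivity threshold passed to [inactive_at()].
#' @return 0, 1 or `NA` (insufficient follow-up).
#' @export
label_window <- function(series, end_day, X, threshold = 28L) {
  stop_if_not(X %in% seq(28L, 91L, by = 7L),
              "X must lie on the 7-day grid 28..91")
  t <- end_day + X
  if (t > series$cutoff_day) return(NA_integer_)
  as.integer(inactive_at(series, t, threshold))
}

#' Segment and label all users' windows
#'
#' Convenience wrapper: segments every series and attaches one label column
#' `y_X` and one defined-flag column `def_X` per horizon in `x_grid`.
#'
#' @param series_list List of `daily_series` from [build_daily_series()].
#' @param x_grid Horizons (default 28..91 by 7).
#' @param window_len Window length in days.
#' @param threshold Inactivity threshold in days.
#' @param drop_empty Drop windows with no measurements?
#' @return data.frame, one row per (user, window).
#' @export
label_windows <- function(series_list, x_grid = seq(28L, 91L, by = 7L),
                          window_len = 14L, threshold = 28L,
                          drop_empty = FALSE) {
  parts <- lapply(series_list, function(s) {
    w <- segment_windows(s, window_len, drop_empty)
    if (nrow(w) == 0L) return(NULL)
    for (X in x_grid) {
      lab <- vapply(w$end_day, function(e) label_window(s, e, X, threshold),
                    NA_integer_)
      w[[paste0("y_", X)]] <- lab
      w[[paste0("def_", X)]] <- !is.na(lab)
    }
    w
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) {
    out <- data.frame(user_id = character(0), start_day = integer(0),
                      end_day = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Detect no-measurement gap episodes
#'
#' One episode per maximal run of unmeasured days that follows a measured
#' day; the trailing run up to the cutoff is included, with its length
#' counted to the cutoff. Each episode records whether measurements were
#' resumed (per [detect_resumption()]) within 180 days of the gap start;
#' that flag is undefined (`NA`) when fewer than 180 days of follow-up
#' remain after the gap start.
#'
#' @param series A `daily_series`.
#' @param resumption_horizon Days after `gap_start` within which resumption
#'   counts (default 180).
#' @return data.frame: `user_id`, `gap_start`, `gap_length`,
#'   `followup_days`, `resumed_within_180`.
#' @export
detect_gaps <- function(series, resumption_horizon = 180L) {
  stop_if_not(inherits(series, "daily_series"), "series must be a daily_series")
  d <- series$days
  starts <- integer(0); lens <- integer(0)
  if (length(d) > 1L) {
    dif <- diff(d)
    idx <- which(dif > 1L)
    starts <- d[idx] + 1L
    lens <- dif[idx] - 1L
  }
  last <- d[length(d)]
  if (last < series$cutoff_day) {
    starts <- c(starts, last + 1L)
    lens <- c(lens, series$cutoff_day - last)
  }
  if (!length(starts)) {
    return(data.frame(user_id = character(0), gap_start = integer(0),
                      gap_length = integer(0), followup_days = integer(0),
                      resumed_within_180 = logical(0),
                      stringsAsFactors = FALSE))
  }
  followup <- series$cutoff_day - starts + 1L
  resumed <- rep(NA, length(starts))
  for (i in seq_along(starts)) {
    if (followup[i] >= resumption_horizon) {
      r <- detect_resumption(series, starts[i] - 1L)
      resumed[i] <- !is.na(r) && r <= starts[i] + resumption_horizon - 1L
    }
  }
  data.frame(user_id = rep(series$user_id, length(starts)),
             gap_start = starts, gap_length = lens,
             followup_days = followup, resumed_within_180 = resumed,
             stringsAsFactors = FALSE)
}

#' Detect resumption of measurement
#'
#' Resumption after `after_day` is the earliest measurement day `r >
#' after_day` such that each of the four consecutive weekly windows
#' `[r, r+6], [r+7, r+13], [r+14, r+20], [r+21, r+27]` contains at least one
#' measurement — i.e. measuring at least once a week for 4 consecutive
#' weeks. A candidate is only accepted when the full 28 days are observable
#' (`r + 27 <= cutoff_day`).
#'
#' @param series A `daily_series`.
#' @param after_day Day after which to search.
#' @return The resumption day index, or `NA_integer_` if none.
#' @export
detect_resumption <- function(series, after_day) {
  stop_if_not(inherits(series, "daily_series"), "series must be a daily_series")
  stop_if_not(after_day <= series$cutoff_day, "after_day exceeds cutoff_day")
  cand <- series$days[series$days > after_day &
                        series$days + 27L <= series$cutoff_day]
  for (r in cand) {
    ok <- TRUE
    for (w in 0:3) {
      if (n_measured_in(series, r + 7L * w, r + 7L * w + 6L) == 0L) {
        ok <- FALSE; break
      }
    }
    if (ok) return(as.integer(r))
  }
  NA_integer_
}

#' First onset of the inactive state
#'
#' Returns the earliest day `t` at which [inactive_at()] is true, i.e. the
#' 28th day of the first gap of at least `threshold` unmeasured days — or
#' `NA` if the user never becomes inactive before the cutoff. This is the
#' "dropout" event time used by the descriptive analyses.
#'
#' @param series A `daily_series`.
#' @param threshold Inactivity threshold in days.
#' @return Day index or `NA_integer_`.
#' @export
first_inactive_onset <- function(series, threshold = 28L) {
  g <- detect_gaps(series)
  hit <- which(g$gap_length >= threshold)
  if (!length(hit)) return(NA_integer_)
  as.integer(g$gap_start[hit[1]] + threshold - 1L)
}
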