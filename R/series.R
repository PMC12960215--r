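#' Build per-user daily measurement series
#'
#' Collapses raw readings into the day-indexed substrate on which all event
#' labeling and feature extraction operate. Multiple same-day readings
#' collapse to one "measured day" for event logic while the per-day reading
#' count and readings themselves are retained for features.
#'
#' @param measurements data.frame with columns `user_id`, `date` (Date or
#'   "YYYY-MM-DD"), `sbp`, `dbp`, `pulse`.
#' @param cutoff_day Last observed day of the dataset as a day index (see
#'   [bp_origin()]). Defaults to the maximum date present.
#' @return A named list of `daily_series` objects, one per user. Each holds
#'   `user_id`, `first_day`, `cutoff_day`, sorted measured `days`, per-day
#'   reading `counts`, and the day-sorted `readings` data.frame.
#' @export
build_daily_series <- function(measurements, cutoff_day = NULL) {
  stop_if_not(is.data.frame(measurements) &&
                all(c("user_id", "date", "sbp", "dbp", "pulse") %in%
                      names(measurements)),
              "measurements must have columns user_id, date, sbp, dbp, pulse")
  if (nrow(measurements) == 0L) return(list())
  day <- date_to_day(measurements$date)
  if (is.null(cutoff_day)) cutoff_day <- max(day)
  cutoff_day <- as.integer(cutoff_day)
  ord <- order(measurements$user_id, day)
  m <- measurements[ord, , drop = FALSE]
  dy <- day[ord]
  split_idx <- split(seq_along(dy), m$user_id)
  lapply(split_idx, function(idx) {
    d <- dy[idx]
    rd <- data.frame(day = d, sbp = m$sbp[idx], dbp = m$dbp[idx],
                     pulse = m$pulse[idx])
    tab <- rle(d)
    new_daily_series(m$user_id[idx[1]], days = tab$values,
                     counts = tab$lengths, readings = rd,
                     cutoff_day = cutoff_day)
  })
}

new_daily_series <- function(user_id, days, counts, readings, cutoff_day) {
  stop_if_not(length(days) >= 1L, "daily_series needs at least one measured day")
  stop_if_not(!is.unsorted(days, strictly = TRUE), "days must be strictly increasing")
  stop_if_not(all(counts >= 1L), "counts must be >= 1 on measured days")
  stop_if_not(max(days) <= cutoff_day, "measured days must not exceed cutoff_day")
  structure(list(user_id = user_id,
                 first_day = as.integer(days[1]),
                 cutoff_day = as.integer(cutoff_day),
                 days = as.integer(days),
                 counts = as.integer(counts),
                 readings = readings),
            class = "daily_series")
}

#' @method print daily_series
#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("daily_series %s: %d measured days (%d readings), days %d..%d, cutoff %d\n",
              x$user_id, length(x$days), sum(x$counts), x$first_day,
              max(x$days), x$cutoff_day))
  invisible(x)
}

# number of measured days in the closed interval [from, to]
n_measured_in <- function(series, from, to) {
  if (to < from) return(0L)
  findInterval(to, series$days) - findInterval(from - 1L, series$days)
}
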