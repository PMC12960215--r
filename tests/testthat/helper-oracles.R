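# Construction helpers and independent brute-force oracles used across the
# suite. The oracles scan every day naively and share no code with the
# package's implementations.

# build a daily_series from measured day indices (one reading per day,
# duplicated days allowed for multi-reading days)
make_series <- function(days, cutoff, user_id = "u1", sbp = NULL) {
  days <- sort(as.integer(days))
  if (is.null(sbp)) sbp <- rep(120, length(days))
  measurements <- data.frame(
    user_id = user_id,
    date = bp_origin() + days,
    sbp = sbp, dbp = round(0.6 * sbp), pulse = 72,
    stringsAsFactors = FALSE
  )
  build_daily_series(measurements, cutoff_day = cutoff)[[user_id]]
}

# naive day-scan: no measurement in [t - threshold + 1, t]
oracle_inactive_at <- function(days, t, threshold = 28L) {
  !any(vapply((t - threshold + 1L):t, function(d) d %in% days, TRUE))
}

oracle_label <- function(days, end_day, X, cutoff, threshold = 28L) {
  if (end_day + X > cutoff) return(NA_integer_)
  as.integer(oracle_inactive_at(days, end_day + X, threshold))
}

# naive run scan over every day of the observation span
oracle_gaps <- function(days, cutoff) {
  first <- min(days)
  measured <- (first:cutoff) %in% days
  out <- NULL
  d <- first + 1L
  while (d <= cutoff) {
    i <- d - first + 1L
    if (!measured[i] && measured[i - 1L]) {
      len <- 0L
      while (d + len <= cutoff && !measured[d + len - first + 1L]) len <- len + 1L
      out <- rbind(out, data.frame(gap_start = d, gap_length = len))
      d <- d + len
    } else d <- d + 1L
  }
  if (is.null(out)) data.frame(gap_start = integer(0), gap_length = integer(0))
  else out
}

# naive resumption: first measured day r > after_day whose four weekly
# windows each contain a measurement, with the 28 days observable
oracle_resumption <- function(days, after_day, cutoff) {
  for (r in sort(days)) {
    if (r <= after_day || r + 27L > cutoff) next
    ok <- TRUE
    for (w in 0:3) {
      win <- (r + 7L * w):(r + 7L * w + 6L)
      if (!any(win %in% days)) { ok <- FALSE; break }
    }
    if (ok) return(r)
  }
  NA_integer_
}

# brute-force product-limit estimator evaluated at time t
oracle_km_incidence <- function(time, event, t) {
  s <- 1
  for (u in sort(unique(time[event == 1 & time <= t]))) {
    n_risk <- sum(time >= u)
    d <- sum(time == u & event == 1)
    s <- s * (1 - d / n_risk)
  }
  1 - s
}

# random short series for oracle-equivalence sweeps
random_series <- function(seed) {
  set.seed(seed)
  cutoff <- sample(40:120, 1)
  first <- sample(0:20, 1)
  p <- runif(1, 0.05, 0.9)
  days <- first + which(runif(cutoff - first + 1L) < p) - 1L
  if (!length(days)) days <- first
  list(days = unique(c(first, days)), cutoff = cutoff)
}
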