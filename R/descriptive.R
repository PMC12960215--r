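#' Probability of not resuming measurements, by gap length
#'
#' For each gap length `d` in `d_grid`, among gap episodes that reached at
#' least `d` consecutive unmeasured days (and have the 180-day resumption
#' flag defined), the fraction that never resumed within 180 days of the
#' gap start. Risk sets nest, so the curve is non-decreasing in `d` up to
#' sampling noise; under the default generator the value near d = 28
#' corresponds to the high non-resumption probability that motivates the
#' 28-day inactivity definition.
#'
#' @param gaps data.frame of gap episodes (rbind of [detect_gaps()] output).
#' @param d_grid Gap lengths to evaluate (default 1..60).
#' @return data.frame `d`, `n_at_risk`, `n_not_resumed`, `value`; `value`
#'   is `NA` where the risk set is empty.
#' @export
non_resumption_curve <- function(gaps, d_grid = 1:60) {
  stop_if_not(all(c("gap_length", "resumed_within_180") %in% names(gaps)),
              "gaps must carry gap_length and resumed_within_180")
  g <- gaps[!is.na(gaps$resumed_within_180), , drop = FALSE]
  out <- data.frame(d = d_grid, n_at_risk = NA_integer_,
                    n_not_resumed = NA_integer_, value = NA_real_)
  for (i in seq_along(d_grid)) {
    at_risk <- g$gap_length >= d_grid[i]
    out$n_at_risk[i] <- sum(at_risk)
    out$n_not_resumed[i] <- sum(at_risk & !g$resumed_within_180)
    out$value[i] <- if (out$n_at_risk[i] > 0)
      out$n_not_resumed[i] / out$n_at_risk[i] else NA_real_
  }
  out
}

#' 180-day dropout rate by age group
#'
#' Among users with at least `horizon` days of follow-up after their first
#' measurement, the fraction per age bin whose first inactive-state onset
#' (first trailing 28-day gap) occurs within `horizon` days of the first
#' measurement. Age is taken at the first measurement.
#'
#' @param users User profiles (`user_id`, `birth_ym`).
#' @param series_list List of `daily_series`.
#' @param horizon Follow-up horizon in days (default 180).
#' @param age_breaks Left-closed bin edges; default decades 18, 30, ..., 80+.
#' @param threshold Inactivity threshold in days.
#' @return data.frame `age_bin`, `n`, `n_dropout`, `rate`; empty bins are
#'   omitted with a warning.
#' @export
dropout_rate_by_age <- function(users, series_list, horizon = 180L,
                                age_breaks = c(18, 30, 40, 50, 60, 70, 80, Inf),
                                threshold = 28L) {
  ids <- intersect(users$user_id, names(series_list))
  rows <- lapply(ids, function(id) {
    s <- series_list[[id]]
    if (s$cutoff_day - s$first_day + 1L < horizon) return(NULL)
    onset <- first_inactive_onset(s, threshold)
    data.frame(
      age = age_at_day(users$birth_ym[users$user_id == id], s$first_day),
      dropout = !is.na(onset) && onset <= s$first_day + horizon - 1L)
  })
  rows <- do.call(rbind, rows)
  stop_if_not(!is.null(rows) && nrow(rows) > 0,
              "no users with sufficient follow-up")
  bin <- cut(rows$age, age_breaks, right = FALSE, include.lowest = TRUE)
  counts <- table(bin)
  if (any(counts == 0)) warning("empty age bins omitted: ",
                                paste(names(counts)[counts == 0], collapse = ", "))
  keep <- levels(bin)[counts > 0]
  out <- do.call(rbind, lapply(keep, function(b) {
    sel <- bin == b
    data.frame(age_bin = b, n = sum(sel), n_dropout = sum(rows$dropout[sel]),
               rate = mean(rows$dropout[sel]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cumulative incidence of first dropout
#'
#' The complement of the product-limit (Kaplan–Meier) survival estimator,
#' stepwise at event times, optionally stratified by group. Event time is
#' days from first measurement to first inactive-state onset; users never
#' reaching the inactive state are censored at the dataset cutoff.
#'
#' @param time Non-negative event/censoring times.
#' @param event 1 = first inactive onset observed, 0 = censored.
#' @param group Optional group label per subject.
#' @return data.frame of class `incidence_curve`: `group`, `time`,
#'   `incidence`, `n_risk`, `n_event`, including a `time = 0` row per
#'   group. Values are non-decreasing in time within group.
#' @export
cumulative_incidence <- function(time, event, group = NULL) {
  stop_if_not(all(time >= 0), "times must be non-negative")
  stop_if_not(all(event %in% c(0, 1)), "event flags must be 0/1")
  if (is.null(group)) group <- rep("all", length(time))
  sf <- survival::survfit(survival::Surv(time, event) ~ grp,
                          data = data.frame(time = time, event = event,
                                            grp = group))
  sm <- summary(sf, censored = TRUE)
  grp_lab <- if (is.null(sm$strata)) rep(unique(group)[1], length(sm$time))
             else sub("^grp=", "", as.character(sm$strata))
  out <- do.call(rbind, lapply(unique(grp_lab), function(g) {
    sel <- grp_lab == g
    data.frame(group = g,
               time = c(0, sm$time[sel]),
               incidence = c(0, 1 - sm$surv[sel]),
               n_risk = c(sum(group == g), sm$n.risk[sel]),
               n_event = c(0, sm$n.event[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("incidence_curve", "data.frame")
  out
}

# step-function evaluation of an incidence curve at times t (one group)
incidence_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 0, curve$incidence[pmax(idx, 1L)])
}

#' Age- and sex-standardised comparison of two cohorts' dropout incidence
#'
#' Direct standardisation: within each stratum (age decade x sex by
#' default), the stratum-specific cumulative-incidence curves of each
#' cohort are computed, then averaged with weights equal to the pooled
#' two-cohort stratum distribution. Strata present in only one cohort are
#' dropped from both, with a warning.
#'
#' @param cohort_A,cohort_B data.frames with `time`, `event`, `age`, `sex`.
#' @param age_breaks Age-stratum edges.
#' @return List of class `standardized_comparison`: `A` and `B`
#'   (data.frames `time`, `incidence` on the pooled event-time grid),
#'   `weights` (per-stratum), `strata_dropped`.
#' @export
standardized_incidence_comparison <- function(cohort_A, cohort_B,
                                              age_breaks = c(18, 30, 40, 50,
                                                             60, 70, 80, Inf)) {
  need <- c("time", "event", "age", "sex")
  stop_if_not(all(need %in% names(cohort_A)) && all(need %in% names(cohort_B)),
              "cohorts need columns time, event, age, sex")
  stratum <- function(df)
    paste(as.character(cut(df$age, age_breaks, right = FALSE,
                           include.lowest = TRUE)), df$sex, sep = ":")
  sA <- stratum(cohort_A); sB <- stratum(cohort_B)
  shared <- intersect(unique(sA), unique(sB))
  stop_if_not(length(shared) > 0, "no common strata between cohorts")
  dropped <- setdiff(union(unique(sA), unique(sB)), shared)
  if (length(dropped))
    warning("strata absent from one cohort dropped from both: ",
            paste(dropped, collapse = "; "))
  keepA <- sA %in% shared; keepB <- sB %in% shared
  w <- table(c(sA[keepA], sB[keepB]))
  w <- w / sum(w)
  grid <- sort(unique(c(cohort_A$time[keepA & cohort_A$event == 1],
                        cohort_B$time[keepB & cohort_B$event == 1])))
  if (!length(grid)) grid <- 0
  adj <- function(df, s, keep) {
    acc <- numeric(length(grid))
    for (st in names(w)) {
      sel <- keep & s == st
      ci <- cumulative_incidence(df$time[sel], df$event[sel])
      acc <- acc + as.numeric(w[st]) * incidence_at(ci, grid)
    }
    data.frame(time = grid, incidence = acc)
  }
  structure(list(A = adj(cohort_A, sA, keepA), B = adj(cohort_B, sB, keepB),
                 weights = w, strata_dropped = dropped),
            class = "standardized_comparison")
}

#' @method print standardized_comparison
#' @export
print.standardized_comparison <- function(x, ...) {
  cat(sprintf("standardised incidence comparison over %d strata, %d time points\n",
              length(x$weights), nrow(x$A)))
  cat(sprintf("  final adjusted incidence: A %.4f vs B %.4f\n",
              x$A$incidence[nrow(x$A)], x$B$incidence[nrow(x$B)]))
  invisible(x)
}

#' Monthly dropout rate
#'
#' Per calendar month: numerator = users whose first inactive-state onset
#' falls in the month; denominator = users at risk at the month start
#' (measured within the preceding 28 days and onset not yet reached).
#'
#' @param series_list List of `daily_series`.
#' @param months Character "YYYY-MM" months to evaluate; defaults to all
#'   months covered by the data.
#' @param threshold Inactivity threshold in days.
#' @return data.frame `month`, `n_at_risk`, `n_dropout`, `rate` (`NA` where
#'   the risk set is empty).
#' @export
monthly_dropout_rate <- function(series_list, months = NULL,
                                 threshold = 28L) {
  stop_if_not(length(series_list) > 0, "series_list is empty")
  onset <- vapply(series_list, first_inactive_onset, NA_integer_,
                  threshold = threshold)
  first <- vapply(series_list, function(s) s$first_day, 0L)
  cutoff <- max(vapply(series_list, function(s) s$cutoff_day, 0L))
  if (is.null(months)) {
    rng <- range(day_to_date(c(min(first), cutoff)))
    months <- format(seq(as.Date(format(rng[1], "%Y-%m-01")), rng[2],
                         by = "month"), "%Y-%m")
  }
  out <- data.frame(month = months, n_at_risk = NA_integer_,
                    n_dropout = NA_integer_, rate = NA_real_,
                    stringsAsFactors = FALSE)
  onset_month <- ifelse(is.na(onset), NA_character_,
                        format(day_to_date(onset), "%Y-%m"))
  for (i in seq_along(months)) {
    ms <- date_to_day(as.Date(paste0(months[i], "-01")))
    at_risk <- vapply(seq_along(series_list), function(j) {
      s <- series_list[[j]]
      if (first[j] > ms - 1L || ms - 1L > s$cutoff_day) return(FALSE)
      if (!is.na(onset[j]) && onset[j] < ms) return(FALSE)
      n_measured_in(s, ms - 28L, ms - 1L) > 0L
    }, TRUE)
    out$n_at_risk[i] <- sum(at_risk)
    out$n_dropout[i] <- sum(at_risk & !is.na(onset_month) &
                              onset_month == months[i])
    out$rate[i] <- if (out$n_at_risk[i] > 0)
      out$n_dropout[i] / out$n_at_risk[i] else NA_real_
  }
  out
}

#' Compare week-over-week measurement change between outcome groups
#'
#' Two-sided Mann–Whitney (Wilcoxon rank-sum) comparison of the
#' week2-minus-week1 measured-day delta between windows that led to
#' dropout at horizon `X` and windows that did not. `scope` selects the
#' whole-week, weekday-only or weekend-only delta.
#'
#' @param features Feature data.frame (from [build_feature_matrix()]).
#' @param labels 0/1 label vector at the chosen horizon, row-aligned with
#'   `features` (`NA` rows are dropped).
#' @param scope `"all"`, `"weekday"` or `"weekend"`.
#' @return data.frame with the scope, rank-sum statistic, two-sided p
#'   value, group medians and sizes.
#' @export
compare_week_delta_by_outcome <- function(features, labels,
                                          scope = c("all", "weekday",
                                                    "weekend")) {
  scope <- match.arg(scope)
  col <- paste0("delta_days_", scope)
  stop_if_not(col %in% names(features), "features lack column ", col)
  ok <- !is.na(labels)
  x <- features[[col]][ok]; y <- labels[ok]
  stop_if_not(any(y == 0) && any(y == 1),
              "both outcome groups must be non-empty")
  ht <- stats::wilcox.test(x[y == 1], x[y == 0], exact = FALSE)
  data.frame(scope = scope, statistic = unname(ht$statistic),
             p_value = ht$p.value,
             median_dropout = stats::median(x[y == 1]),
             median_continuation = stats::median(x[y == 0]),
             n_dropout = sum(y == 1), n_continuation = sum(y == 0),
             stringsAsFactors = FALSE)
}
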