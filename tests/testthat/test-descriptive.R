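test_that("non-resumption curve counts nested risk sets correctly", {
  gaps <- data.frame(gap_length = c(10, 30, 40),
                     resumed_within_180 = c(TRUE, FALSE, FALSE))
  nr <- non_resumption_curve(gaps, d_grid = c(5, 28))
  expect_equal(nr$value, c(2 / 3, 1))
  expect_identical(nr$n_at_risk, c(3L, 2L))

  all_resumed <- data.frame(gap_length = 5:30,
                            resumed_within_180 = TRUE)
  expect_true(all(non_resumption_curve(all_resumed, 1:5)$value == 0))
  none_resumed <- data.frame(gap_length = 5:30,
                             resumed_within_180 = FALSE)
  expect_true(all(non_resumption_curve(none_resumed, 1:5)$value == 1))
  # empty risk set reported as NA, not dropped
  expect_true(is.na(non_resumption_curve(all_resumed, 40)$value))
})

test_that("product-limit incidence reproduces the hand-computed example", {
  ci <- cumulative_incidence(c(10, 15, 20, 25, 30), c(1, 0, 1, 0, 1))
  expect_equal(bpdropout:::incidence_at(ci, 10), 0.2, tolerance = 1e-9)
  expect_equal(bpdropout:::incidence_at(ci, 20), 1 - 0.8 * (2 / 3),
               tolerance = 1e-9)
  expect_equal(bpdropout:::incidence_at(ci, 30), 1, tolerance = 1e-9)

  none <- cumulative_incidence(c(5, 8, 12), c(0, 0, 0))
  expect_true(all(none$incidence == 0))
  expect_error(cumulative_incidence(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("incidence matches a brute-force estimator on random samples", {
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(3:25, 1)
    time <- sample(1:40, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    ci <- cumulative_incidence(time, event)
    for (t in sample(0:45, 5)) {
      expect_equal(bpdropout:::incidence_at(ci, t),
                   oracle_km_incidence(time, event, t), tolerance = 1e-12)
    }
  }
})

test_that("time rescaling shifts the time axis only", {
  time <- c(3, 7, 9, 12); event <- c(1, 0, 1, 1)
  a <- cumulative_incidence(time, event)
  b <- cumulative_incidence(2 * time, event)
  expect_equal(b$time, 2 * a$time)
  expect_equal(b$incidence, a$incidence)
})

test_that("age-binned dropout rates hit the degenerate endpoints", {
  mk_user <- function(id, birth, days, cutoff) {
    m <- data.frame(user_id = id, date = bp_origin() + days,
                    sbp = 120, dbp = 80, pulse = 70)
    list(users = data.frame(user_id = id, birth_ym = birth, sex = "male",
                            regime = "A"), m = m, cutoff = cutoff)
  }
  births <- c("1995-01", "1980-01", "1960-01", "1940-01")
  specs <- lapply(seq_along(births), function(i)
    mk_user(paste0("u", i), births[i], 0:4, 250))
  users <- do.call(rbind, lapply(specs, `[[`, "users"))
  meas <- do.call(rbind, lapply(specs, `[[`, "m"))
  series <- build_daily_series(meas, cutoff_day = 250L)
  expect_warning(rt <- dropout_rate_by_age(users, series), "empty age bins")
  expect_true(all(rt$rate == 1))  # everyone stops at day 4

  daily <- build_daily_series(
    do.call(rbind, lapply(seq_along(births), function(i)
      data.frame(user_id = paste0("u", i), date = bp_origin() + 0:200,
                 sbp = 120, dbp = 80, pulse = 70))),
    cutoff_day = 200L)
  expect_warning(rt0 <- dropout_rate_by_age(users, daily), "empty age bins")
  expect_true(all(rt0$rate == 0))
})

test_that("standardisation is exact in the degenerate cases", {
  set.seed(15)
  coh <- data.frame(time = sample(10:200, 300, replace = TRUE),
                    event = rbinom(300, 1, 0.5),
                    age = runif(300, 20, 90),
                    sex = sample(c("male", "female"), 300, replace = TRUE))
  # identical cohorts give identical adjusted curves
  cmp <- standardized_incidence_comparison(coh, coh)
  expect_equal(cmp$A, cmp$B)
  # one stratum: adjusted curve equals the crude estimator
  one <- coh; one$age <- 50; one$sex <- "male"
  cmp1 <- standardized_incidence_comparison(one, one)
  crude <- cumulative_incidence(one$time, one$event)
  expect_equal(cmp1$A$incidence,
               bpdropout:::incidence_at(crude, cmp1$A$time),
               tolerance = 1e-12)
  # disjoint strata are an error
  m <- coh; m$sex <- "male"; f <- coh; f$sex <- "female"
  m$age <- 30; f$age <- 70
  expect_error(standardized_incidence_comparison(m, f), "common strata")
})

test_that("monthly dropout rates hit the degenerate endpoints", {
  daily <- build_daily_series(
    data.frame(user_id = "u1", date = bp_origin() + 0:120,
               sbp = 120, dbp = 80, pulse = 70), cutoff_day = 120L)
  mr <- monthly_dropout_rate(daily)
  expect_true(all(mr$rate[!is.na(mr$rate)] == 0))

  # one user measuring through January then stopping: onset in February
  stopper <- build_daily_series(
    data.frame(user_id = "u1", date = bp_origin() + 0:20,
               sbp = 120, dbp = 80, pulse = 70), cutoff_day = 150L)
  onset_month <- format(bp_origin() + 20 + 28, "%Y-%m")
  mr2 <- monthly_dropout_rate(stopper)
  expect_identical(mr2$rate[mr2$month == onset_month], 1)
})

test_that("week-delta comparison separates shifted groups", {
  f_same <- data.frame(delta_days_all = rep(c(-2, 0, 1, 3), 50))
  y_half <- rep(c(0, 1), each = 100)  # both groups see the same values
  same <- compare_week_delta_by_outcome(f_same, y_half, "all")
  expect_gt(same$p_value, 0.9)
  expect_identical(same$median_dropout, same$median_continuation)

  f_shift <- data.frame(delta_days_weekday = c(rnorm(100, 3), rnorm(100, -3)))
  y_shift <- rep(c(0, 1), each = 100)
  shifted <- compare_week_delta_by_outcome(f_shift, y_shift, "weekday")
  expect_lt(shifted$p_value, 0.001)
  expect_lt(shifted$median_dropout, shifted$median_continuation)

  expect_error(compare_week_delta_by_outcome(f_same, rep(1, 200), "all"),
               "both outcome groups")
})

test_that("pre-dropout decline separates outcome groups in every scope", {
  fx <- feature_cohort()
  labs <- fx$windows$y_56
  for (sc in c("all", "weekday", "weekend")) {
    r <- compare_week_delta_by_outcome(fx$features, labs, sc)
    expect_lt(r$p_value, 0.001)
    expect_lte(r$median_dropout, r$median_continuation)
    # the shift is downward: windows preceding dropout lose measurement days
    col <- paste0("delta_days_", sc)
    ok <- !is.na(labs)
    expect_lt(mean(fx$features[[col]][ok][labs[ok] == 1]),
              mean(fx$features[[col]][ok][labs[ok] == 0]))
  }
})
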