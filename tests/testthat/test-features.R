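profile_male <- list(sex = "male", birth_ym = "1970-06")

test_that("feature catalogue is a stable, complete schema", {
  cat_df <- feature_catalogue()
  expect_gte(nrow(cat_df), 30L)
  expect_identical(anyDuplicated(cat_df$name), 0L)
  expect_true(all(cat_df$group %in% c("pattern", "vitals", "demographic")))
  expect_identical(sum(table(cat_df$group)), nrow(cat_df))

  # every extracted feature appears exactly once, in catalogue order
  s <- make_series(0:13, cutoff = 27)
  fv <- extract_features(s, list(start_day = 0L, end_day = 13L), profile_male)
  expect_identical(names(fv), cat_df$name)

  # the serialized catalogue round-trips losslessly
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cat_df, path, row.names = FALSE)
  expect_identical(utils::read.csv(path, stringsAsFactors = FALSE), cat_df)
})

test_that("empty and constant windows produce the documented values", {
  # a user who measured before but not inside the second window
  s <- make_series(0:5, cutoff = 60)
  fv <- extract_features(s, list(start_day = 14L, end_day = 27L), profile_male)
  expect_identical(unname(fv["n_meas_total"]), 0)
  expect_identical(unname(fv["n_days_measured"]), 0)
  expect_identical(unname(fv["delta_days_all"]), 0)
  expect_true(all(is.na(fv[c("sbp_mean", "sbp_sd", "sbp_min", "sbp_max",
                             "sbp_last_minus_first", "sbp_slope_per_day",
                             "meas_per_measured_day")])))

  # one reading per day for 14 days at constant 120 mmHg
  s <- make_series(0:13, cutoff = 13, sbp = rep(120, 14))
  fv <- extract_features(s, list(start_day = 0L, end_day = 13L), profile_male)
  expect_identical(unname(fv["n_days_measured"]), 14)
  expect_identical(unname(fv["delta_days_all"]), 0)
  expect_identical(unname(fv[c("sbp_mean", "sbp_min", "sbp_max")]),
                   c(120, 120, 120))
  expect_identical(unname(fv["sbp_sd"]), 0)
  expect_identical(unname(fv["sbp_slope_per_day"]), 0)
  expect_identical(unname(fv["longest_streak"]), 14)
  expect_identical(unname(fv["max_gap_in_window"]), 0)
})

test_that("week and weekday deltas follow the Monday-anchored calendar", {
  # window starts day 0 (a Monday); readings on window days 1,2,3 and 8
  s <- make_series(c(0, 1, 2, 7), cutoff = 13)
  fv <- extract_features(s, list(start_day = 0L, end_day = 13L), profile_male)
  expect_identical(unname(fv["n_days_week1"]), 3)
  expect_identical(unname(fv["n_days_week2"]), 1)
  expect_identical(unname(fv["delta_days_all"]), -2)
  expect_identical(unname(fv["delta_days_weekday"]), -2)
  expect_identical(unname(fv["delta_days_weekend"]), 0)
})

test_that("age and sex encodings are exact on boundary months", {
  s <- make_series(0:13, cutoff = 13)
  w <- list(start_day = 0L, end_day = 13L)
  # window end = origin + 13 days = 2017-01-15
  fv <- extract_features(s, w, list(sex = "female", birth_ym = "1967-01"))
  manual <- as.numeric(as.Date("2017-01-15") - as.Date("1967-01-01")) / 365.25
  expect_equal(unname(fv["age_years"]), manual, tolerance = 1e-12)
  expect_identical(unname(fv[c("is_female", "sex_provided")]), c(1, 1))
  fv <- extract_features(s, w, list(sex = "unspecified", birth_ym = "1990-02"))
  expect_identical(unname(fv[c("is_female", "sex_provided")]), c(0, 0))
})

test_that("feature vector is invariant to record order and matches brute force", {
  set.seed(42)
  for (rep in 1:10) {
    days <- sort(sample(0:27, sample(3:20, 1)))
    sbp <- round(rnorm(length(days), 130, 10))
    m <- data.frame(user_id = "u1", date = bp_origin() + days,
                    sbp = sbp, dbp = round(0.6 * sbp), pulse = 70)
    perm <- m[sample(nrow(m)), ]
    s1 <- build_daily_series(m, cutoff_day = 27L)[["u1"]]
    s2 <- build_daily_series(perm, cutoff_day = 27L)[["u1"]]
    w <- segment_windows(s1)[1, ]
    f1 <- extract_features(s1, w, profile_male)
    f2 <- extract_features(s2, w, profile_male)
    expect_identical(f1, f2)
    in_win <- days >= w$start_day & days <= w$end_day
    expect_identical(unname(f1["sbp_max"]), max(sbp[in_win]))
    expect_identical(unname(f1["sbp_min"]), min(sbp[in_win]))
  }
})

test_that("mismatched window and user are rejected", {
  s <- make_series(0:13, cutoff = 13)
  expect_error(
    extract_features(s, list(user_id = "someone_else", start_day = 0L,
                             end_day = 13L), profile_male),
    "mismatch")
})

test_that("additivity decompositions hold on a full generated cohort", {
  fx <- feature_cohort()
  fm <- fx$features
  expect_identical(fm$n_days_week1 + fm$n_days_week2, fm$n_days_measured)
  expect_identical(fm$delta_days_weekday + fm$delta_days_weekend,
                   fm$delta_days_all)
  expect_true(all(fm$n_days_measured >= 0 & fm$n_days_measured <= 14))
  # vital stats are jointly defined or jointly missing, and ordered
  has <- !is.na(fm$sbp_mean)
  expect_identical(has, fm$n_meas_total > 0)
  expect_true(all(fm$sbp_max[has] >= fm$sbp_mean[has]))
  expect_true(all(fm$sbp_mean[has] >= fm$sbp_min[has]))
})
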