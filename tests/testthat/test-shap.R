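# wrap a hand-built xgboost booster as a dropout_model so the attribution
# engine can be probed on minimal ensembles
wrap_booster <- function(fit, feature_names) {
  structure(list(model_type = "gbt", fit = fit,
                 feature_names = feature_names),
            class = c("dropout_gbt", "dropout_model"))
}

train_raw_gbt <- function(x, y, params, nrounds) {
  d <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(params = c(list(objective = "binary:logistic",
                                     nthread = 1, seed = 1), params),
                     data = d, nrounds = nrounds, verbose = 0)
}

test_that("constant (no-split) ensembles attribute nothing", {
  set.seed(1)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  xc <- x; xc[] <- 1  # constant features force single-leaf trees
  fit <- train_raw_gbt(xc, rbinom(40, 1, 0.5), list(max_depth = 3), 5)
  m <- wrap_booster(fit, c("a", "b"))
  rep <- compute_attributions(m, xc)
  expect_true(all(rep$attributions == 0))
  expect_equal(rep$base_value + rowSums(rep$attributions), rep$margin,
               tolerance = 1e-12)
})

test_that("a depth-1 stump attributes only its split feature", {
  set.seed(2)
  x <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(x[, "a"] > 0)
  fit <- train_raw_gbt(x, y, list(max_depth = 1), 1)
  m <- wrap_booster(fit, c("a", "b"))
  rep <- compute_attributions(m, x)
  expect_true(all(rep$attributions[, "b"] == 0))
  expect_equal(rep$attributions[, "a"], rep$margin - rep$base_value,
               tolerance = 1e-12)
  # two-leaf closed form: phi = value(leaf(x)) - cover-weighted mean
  tr <- as.data.frame(xgboost::xgb.model.dt.tree(model = fit))
  leaves <- tr[tr$Feature == "Leaf", ]
  expected_base <- sum(leaves$Gain * leaves$Cover) / sum(leaves$Cover)
  expect_equal(rep$base_value - stats::qlogis(
    as.numeric(xgboost::xgb.config(fit)$learner$learner_model_param$base_score)),
    expected_base, tolerance = 1e-9)
})

test_that("linear attributions equal coefficient times centred value", {
  set.seed(3)
  x <- matrix(rnorm(1200), 300, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(300, 1, plogis(x[, 1] - 0.5 * x[, 3]))
  user <- sprintf("u%02d", rep(1:75, each = 4))
  m <- fit_dropout_model(x, y, user, "logistic", budget_trials = 2, seed = 4)
  rep <- compute_attributions(m, x)
  b <- coef(m)
  z <- bpdropout:::impute_scale(x, m$impute_means, m$center, m$scale)
  for (j in 1:4) {
    expect_equal(rep$attributions[, j], unname(b[j + 1] * z[, j]),
                 tolerance = 1e-12)
  }
  expect_equal(rep$base_value + rowSums(rep$attributions), rep$margin,
               tolerance = 1e-12)
})

test_that("tree attributions match xgboost's reference within float32 noise", {
  set.seed(5)
  n <- 800
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(n, 1, plogis(2 * x[, 1] + x[, 2]^2 - 1))
  x[sample(length(x), 200)] <- NA  # exercise missing-value routing
  fit <- train_raw_gbt(x, y, list(max_depth = 4, eta = 0.2,
                                  subsample = 0.8), 60)
  m <- wrap_booster(fit, paste0("f", 1:5))
  rep <- compute_attributions(m, x)
  ref <- predict(fit, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
  expect_lt(max(abs(rep$attributions - ref[, 1:5])), 1e-3)
  expect_lt(max(abs(rep$margin -
                      predict(fit, xgboost::xgb.DMatrix(x),
                              outputmargin = TRUE))), 1e-4)
  # double-precision local accuracy, far tighter than the float32 reference
  expect_lt(max(abs(rep$base_value + rowSums(rep$attributions) - rep$margin)),
            1e-10)
})

test_that("feature ranking orders by mean absolute attribution", {
  set.seed(6)
  x <- matrix(rnorm(2000), 500, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(500, 1, plogis(3 * x[, 2]))
  user <- sprintf("u%03d", rep(1:125, each = 4))
  m <- fit_dropout_model(x, y, user, "gbt", budget_trials = 2, seed = 7)
  rep <- compute_attributions(m, x)
  rk <- rank_features(rep)
  expect_identical(rk$feature[1], "f2")
  expect_identical(sort(rk$feature), sort(paste0("f", 1:4)))
  expect_true(all(diff(rk$mean_abs_attribution) <= 0))
  expect_error(rank_features(rep, top_k = 0), "top_k")
})

test_that("dependence profiles bin correctly and detect planted shapes", {
  # hand-built report: quadratic attribution of x on [-1, 1]
  n <- 2000L
  set.seed(8)
  xv <- runif(n, -1, 1)
  rep <- structure(list(
    attributions = matrix(xv^2, ncol = 1, dimnames = list(NULL, "x")),
    base_value = 0, margin = xv^2,
    x = matrix(xv, ncol = 1, dimnames = list(NULL, "x")),
    feature_names = "x", model_type = "gbt"), class = "shap_report")
  prof <- dependence_profile(rep, "x", n_bins = 10)
  expect_identical(sum(prof$n), n)
  expect_true(all(diff(prof$lo) > 0))
  u <- detect_ushape(prof, -0.5, c(-0.2, 0.2), 0.5)
  expect_true(u$ushape)
  expect_gt(u$low_margin, 0)
  expect_gt(u$high_margin, 0)

  # single bin equals the overall mean
  p1 <- dependence_profile(rep, "x", n_bins = 1)
  expect_identical(nrow(p1), 1L)
  expect_equal(p1$mean_attribution, mean(xv^2), tolerance = 1e-12)

  # linear attribution is not U-shaped (one tail below the middle)
  rep$attributions[, 1] <- xv
  prof_lin <- dependence_profile(rep, "x")
  expect_false(detect_ushape(prof_lin, -0.5, c(-0.2, 0.2), 0.5)$ushape)

  # constant attribution: every bin mean equals the constant
  rep$attributions[, 1] <- 0.7
  prof_c <- dependence_profile(rep, "x")
  expect_true(all(abs(prof_c$mean_attribution - 0.7) < 1e-12))

  # empty extreme region is undefined, not false
  expect_warning(u2 <- detect_ushape(prof_c, -2, c(-0.2, 0.2), 2),
                 "undefined")
  expect_true(is.na(u2$ushape))
})
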