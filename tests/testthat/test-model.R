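# small synthetic design matrices for learner-level checks
toy_matrix <- function(n, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x
}

test_that("cohort split is user-level, size-matched and deterministic", {
  users <- data.frame(user_id = sprintf("u%03d", 1:100),
                      regime = rep(c("A", "B"), c(10, 90)))
  sp <- split_cohorts(users, seed = 4)
  expect_identical(length(sp$test1), 10L)
  expect_identical(length(sp$test2), 10L)
  expect_identical(length(sp$train), 80L)
  expect_identical(length(intersect(sp$test1, sp$test2)), 0L)
  expect_identical(length(intersect(sp$train, sp$test2)), 0L)
  expect_identical(split_cohorts(users, seed = 4), sp)
  expect_false(identical(split_cohorts(users, seed = 5)$test2, sp$test2))

  flipped <- data.frame(user_id = users$user_id,
                        regime = rep(c("A", "B"), c(60, 40)))
  expect_error(split_cohorts(flipped), "cannot match sizes")
  expect_error(split_cohorts(data.frame(user_id = "u1", regime = "A")),
               "both regimes")
})

test_that("AUC rank statistic handles the canonical cases and ties", {
  expect_identical(auc_rank(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_identical(auc_rank(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # 4 positive-negative pairs: 3 concordant, 1 discordant
  expect_identical(auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc_rank(1:3, c(1, 1, 1)), "single class")
})

test_that("rank AUC equals trapezoidal ROC integration and pROC", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, y), sample(c(1, 2, Inf), 1))  # induce ties
    roc <- roc_points(s, y)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(auc_rank(s, y), bpdropout:::trapezoid_auc(roc),
                 tolerance = 1e-9)
  }
  skip_if_not_installed("pROC")
  y <- rbinom(300, 1, 0.5); s <- rnorm(300, y)
  expect_equal(auc_rank(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("grouped folds never split a user's rows across train/validation", {
  user <- rep(sprintf("u%02d", 1:30), each = 4)
  set.seed(1)
  fold <- bpdropout:::grouped_folds(user, 5)
  expect_identical(length(fold), length(user))
  per_user_folds <- tapply(fold, user, function(f) length(unique(f)))
  expect_true(all(per_user_folds == 1))
  expect_identical(sort(unique(fold)), 1:5)
})

test_that("a perfectly separable toy reaches AUC 1 for both learners", {
  x <- toy_matrix(400, seed = 2)
  # a clear margin around the decision boundary keeps any reasonable
  # split threshold on the right side of every held-out point
  x[, "f1"] <- x[, "f1"] + 0.5 * sign(x[, "f1"])
  y <- as.integer(x[, "f1"] > 0)
  user <- rep(sprintf("u%03d", 1:100), each = 4)
  for (mt in c("gbt", "logistic")) {
    fit <- fit_dropout_model(x, y, user, model_type = mt,
                             budget_trials = 2, seed = 3)
    expect_identical(fit$cv_auc_mean, 1)
    ev <- evaluate_auc(fit, x, y)
    expect_identical(ev$auc, 1)
  }
})

test_that("permuted labels give chance-level cross-validated AUC", {
  x <- toy_matrix(2400, p = 8, seed = 4)
  set.seed(5)
  y <- sample(rep(0:1, 1200))
  user <- rep(sprintf("u%03d", 1:600), each = 4)
  for (mt in c("gbt", "logistic")) {
    fit <- fit_dropout_model(x, y, user, model_type = mt,
                             budget_trials = 2, seed = 6)
    expect_lt(abs(fit$cv_auc_mean - 0.5), 0.05)
  }
})

test_that("refitting with the same seed reproduces the model exactly", {
  x <- toy_matrix(300, seed = 7)
  y <- rbinom(300, 1, plogis(x[, "f2"]))
  user <- rep(sprintf("u%02d", 1:75), each = 4)
  for (mt in c("gbt", "logistic")) {
    a <- fit_dropout_model(x, y, user, model_type = mt,
                           budget_trials = 3, seed = 11)
    b <- fit_dropout_model(x, y, user, model_type = mt,
                           budget_trials = 3, seed = 11)
    expect_identical(a$best_params, b$best_params)
    expect_equal(predict(a, x, type = "margin"),
                 predict(b, x, type = "margin"), tolerance = 1e-6)
    expect_equal(evaluate_auc(a, x, y)$auc, evaluate_auc(b, x, y)$auc,
                 tolerance = 1e-6)
  }
})

test_that("degenerate training inputs are rejected", {
  x <- toy_matrix(40, seed = 9)
  user <- sprintf("u%02d", rep(1:10, each = 4))
  expect_error(fit_dropout_model(x, rep(1, 40), user), "both classes")
  expect_error(fit_dropout_model(x, rep(0:1, 20), user, budget_trials = 0),
               "budget_trials")
  fit <- fit_dropout_model(x, rep(0:1, 20), user, budget_trials = 1, seed = 1)
  expect_error(predict(fit, x[, 1:3]), "schema mismatch")
})

test_that("logistic coefficients are exposed; tree coefficients are not", {
  x <- toy_matrix(200, seed = 10)
  y <- rbinom(200, 1, plogis(2 * x[, "f1"]))
  user <- sprintf("u%02d", rep(1:50, each = 4))
  lg <- fit_dropout_model(x, y, user, "logistic", budget_trials = 2, seed = 1)
  b <- coef(lg)
  expect_identical(names(b)[1], "(Intercept)")
  expect_gt(b["f1"], 0)
  gb <- fit_dropout_model(x, y, user, "gbt", budget_trials = 1, seed = 1)
  expect_error(coef(gb), "logistic")
})

test_that("horizon sweep excludes undefined labels per horizon only", {
  fx <- feature_cohort()
  users <- fx$cohort$users
  sp <- split_cohorts(users, seed = 2)
  sw <- horizon_sweep(fx$features, fx$windows, sp, x_grid = 56L,
                      model_types = "logistic", budget_trials = 2, seed = 2)
  expect_identical(nrow(sw$report), 1L)
  expect_identical(sw$report$n_train,
                   sum(!is.na(fx$windows$y_56) &
                         fx$windows$user_id %in% sp$train))
  expect_error(horizon_sweep(fx$features, fx$windows, sp,
                             x_grid = integer(0)), "non-empty")
})
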