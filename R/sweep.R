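#' Train and evaluate dropout models across prediction horizons
#'
#' For every horizon `X` in `x_grid` and every requested model family, rows
#' whose label at `X` is undefined (insufficient follow-up) are excluded
#' for that horizon only, an independent model is tuned and trained on the
#' training users, and AUC is evaluated on the two held-out user sets of
#' the split plan.
#'
#' @param features Feature data.frame from [build_feature_matrix()]
#'   (carries `user_id`).
#' @param labels Labeled-window data.frame from [label_windows()], row-aligned
#'   with `features`.
#' @param split A `split_plan` from [split_cohorts()].
#' @param x_grid Horizons to sweep (non-empty, on the 7-day grid 28..91).
#' @param model_types Subset of `c("gbt", "logistic")`.
#' @param n_folds,budget_trials,seed Passed to [fit_dropout_model()].
#' @param keep_models Keep the fitted models on the returned object?
#' @return Object of class `horizon_sweep`: `report` (one row per horizon
#'   and model: CV mean/sd AUC, test1/test2 AUC, row counts), `models`
#'   (named list, `"<type>_<X>"`), `rocs` (test-2 ROC point sets).
#' @export
horizon_sweep <- function(features, labels, split,
                          x_grid = seq(28L, 91L, by = 7L),
                          model_types = c("gbt", "logistic"),
                          n_folds = 5L, budget_trials = 20L, seed = 1L,
                          keep_models = TRUE) {
  stop_if_not(length(x_grid) >= 1L, "x_grid must be non-empty")
  stop_if_not(inherits(split, "split_plan"), "split must be a split_plan")
  stop_if_not(nrow(features) == nrow(labels),
              "features and labels must be row-aligned")
  model_types <- match.arg(model_types, c("gbt", "logistic"),
                           several.ok = TRUE)
  report <- NULL; models <- list(); rocs <- list()
  for (X in x_grid) {
    ycol <- paste0("y_", X)
    stop_if_not(ycol %in% names(labels), "labels lack column ", ycol)
    defined <- !is.na(labels[[ycol]])
    uid <- labels$user_id
    tr <- defined & uid %in% split$train
    t1 <- defined & uid %in% split$test1
    t2 <- defined & uid %in% split$test2
    y <- labels[[ycol]]
    for (mt in model_types) {
      fit <- fit_dropout_model(features[tr, , drop = FALSE], y[tr], uid[tr],
                               model_type = mt, n_folds = n_folds,
                               budget_trials = budget_trials,
                               seed = seed + X)
      e1 <- evaluate_auc(fit, features[t1, , drop = FALSE], y[t1])
      e2 <- evaluate_auc(fit, features[t2, , drop = FALSE], y[t2])
      report <- rbind(report, data.frame(
        horizon = X, model_type = mt,
        cv_auc_mean = fit$cv_auc_mean, cv_auc_sd = fit$cv_auc_sd,
        auc_test1 = e1$auc, auc_test2 = e2$auc,
        n_train = sum(tr), n_test1 = sum(t1), n_test2 = sum(t2),
        stringsAsFactors = FALSE))
      key <- paste0(mt, "_", X)
      if (keep_models) models[[key]] <- fit
      rocs[[key]] <- e2$roc
    }
  }
  rownames(report) <- NULL
  structure(list(report = report, models = models, rocs = rocs,
                 x_grid = x_grid, split = split),
            class = "horizon_sweep")
}

#' @method print horizon_sweep
#' @export
print.horizon_sweep <- function(x, ...) {
  cat("Horizon sweep (AUC by prediction horizon)\n")
  print(x$report, digits = 4)
  invisible(x)
}

#' Plot AUC against prediction horizon
#'
#' @param x A `horizon_sweep`.
#' @param which Test set to plot (`"auc_test2"`, `"auc_test1"` or
#'   `"cv_auc_mean"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.horizon_sweep <- function(x, which = "auc_test2", ...) {
  rep <- x$report
  types <- unique(rep$model_type)
  cols <- stats::setNames(seq_along(types) + 1L, types)
  plot(range(rep$horizon), range(rep[[which]]), type = "n",
       xlab = "prediction horizon X (days)", ylab = "ROC-AUC", ...)
  for (mt in types) {
    r <- rep[rep$model_type == mt, ]
    graphics::lines(r$horizon, r[[which]], type = "b", col = cols[[mt]],
                    pch = 19)
  }
  graphics::legend("bottomleft", legend = types, col = cols, lty = 1,
                   pch = 19, bty = "n")
  invisible(x)
}
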