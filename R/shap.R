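#' Additive feature attributions for a fitted dropout model
#'
#' Computes per-row, per-feature attributions in log-odds units satisfying
#' local accuracy: `base_value + sum(attributions) == margin` for every
#' row, to double rounding error. For the tree model this is path-dependent
#' exact TreeSHAP evaluated in double precision over the dumped ensemble
#' (deterministic, no sampling); for the logistic model the attributions
#' are the exact linear ones, `beta_j * (x_j - mean_j)` with the training
#' means as background.
#'
#' @param model A `dropout_model`.
#' @param newdata Rows to explain (feature data.frame or matrix matching
#'   the training schema; mismatch is an error).
#' @return Object of class `shap_report`: `attributions` (rows x features
#'   matrix), `base_value`, `margin` (per-row model margin recomputed in
#'   double precision), `x` (the conformed feature matrix),
#'   `feature_names`, `model_type`.
#' @export
compute_attributions <- function(model, newdata) {
  stop_if_not(inherits(model, "dropout_model"), "model must be a dropout_model")
  xm <- conform_features(model, newdata)
  if (model$model_type == "gbt") {
    trees <- parse_xgb_trees(model$fit, model$feature_names)
    res <- cpp_treeshap(trees$trees, xm)
    intercept <- trees$intercept
    phi <- res$phi
    base <- intercept + res$base
    margin <- intercept + res$margin
  } else {
    z <- impute_scale(xm, model$impute_means, model$center, model$scale)
    b <- coef(model)
    beta <- b[-1]
    phi <- sweep(z, 2, beta, "*")
    base <- unname(b[1])
    margin <- base + rowSums(phi)
  }
  colnames(phi) <- model$feature_names
  structure(list(attributions = phi, base_value = base, margin = margin,
                 x = xm, feature_names = model$feature_names,
                 model_type = model$model_type),
            class = "shap_report")
}

#' @method print shap_report
#' @export
print.shap_report <- function(x, ...) {
  cat(sprintf("shap_report (%s): %d rows x %d features, base value %.4f\n",
              x$model_type, nrow(x$attributions), ncol(x$attributions),
              x$base_value))
  top <- utils::head(rank_features(x, top_k = 5L), 5L)
  cat("top features by mean |attribution|:\n")
  print(top, digits = 4)
  invisible(x)
}

# flatten an xgboost booster into the array form cpp_treeshap consumes;
# the intercept is recovered from the learner's base_score
parse_xgb_trees <- function(fit, feature_names) {
  df <- as.data.frame(xgboost::xgb.model.dt.tree(model = fit))
  node_num <- function(id) as.integer(sub("^[0-9]+-", "", id))
  trees <- lapply(split(df, df$Tree), function(tr) {
    tr <- tr[order(tr$Node), , drop = FALSE]
    leaf <- tr$Feature == "Leaf"
    feature <- ifelse(leaf, -1L, match(tr$Feature, feature_names) - 1L)
    stop_if_not(!anyNA(feature), "tree uses a feature outside the schema")
    list(feature = as.integer(feature),
         threshold = ifelse(leaf, 0, tr$Split),
         yes = ifelse(leaf, 0L, node_num(tr$Yes)),
         no = ifelse(leaf, 0L, node_num(tr$No)),
         miss = ifelse(leaf, 0L, node_num(tr$Missing)),
         value = ifelse(leaf, tr$Gain, 0),
         cover = tr$Cover)
  })
  cfg <- xgboost::xgb.config(fit)
  bs <- as.numeric(cfg$learner$learner_model_param$base_score)
  list(trees = unname(trees), intercept = stats::qlogis(bs))
}

#' Rank features by mean absolute attribution
#'
#' @param report A `shap_report`.
#' @param top_k Number of features to return (default all).
#' @return data.frame `rank`, `feature`, `mean_abs_attribution`, sorted
#'   descending; ties keep catalogue (column) order.
#' @export
rank_features <- function(report, top_k = ncol(report$attributions)) {
  stop_if_not(inherits(report, "shap_report"), "report must be a shap_report")
  stop_if_not(top_k >= 1L, "top_k must be >= 1")
  m <- colMeans(abs(report$attributions))
  ord <- order(-m)  # stable: ties keep column order
  k <- min(top_k, length(m))
  data.frame(rank = seq_len(k),
             feature = report$feature_names[ord][seq_len(k)],
             mean_abs_attribution = unname(m[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' Binned dependence profile of a feature's attributions
#'
#' Summarises how a feature's attribution varies with its value:
#' equal-count (quantile) bins by default, per-bin mean attribution and
#' count, optionally the per-bin mean of a second (colour-by) feature.
#'
#' @param report A `shap_report`.
#' @param feature Feature name.
#' @param n_bins Number of quantile bins (default 20).
#' @param color_by Optional second feature name.
#' @return Object of class `dependence_profile`: a data.frame with `lo`,
#'   `hi`, `center`, `n`, `mean_attribution` (and `color_mean`), plus the
#'   raw (value, attribution) pairs as an attribute for threshold-based
#'   tests.
#' @export
dependence_profile <- function(report, feature, n_bins = 20L,
                               color_by = NULL) {
  stop_if_not(inherits(report, "shap_report"), "report must be a shap_report")
  stop_if_not(feature %in% report$feature_names,
              "feature not in the model schema: ", feature)
  x <- report$x[, feature]
  a <- report$attributions[, feature]
  ok <- !is.na(x)
  stop_if_not(any(ok), "feature is missing on every row: ", feature)
  x <- x[ok]; a <- a[ok]
  cb <- if (!is.null(color_by)) {
    stop_if_not(color_by %in% report$feature_names,
                "color_by not in the model schema")
    report$x[ok, color_by]
  }
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) edges <- c(edges - 0.5, edges + 0.5)
  bin <- cut(x, edges, include.lowest = TRUE, labels = FALSE)
  idx <- split(seq_along(x), bin)
  prof <- data.frame(
    lo = edges[as.integer(names(idx))],
    hi = edges[as.integer(names(idx)) + 1L],
    center = vapply(idx, function(i) mean(x[i]), 0),
    n = lengths(idx),
    mean_attribution = vapply(idx, function(i) mean(a[i]), 0))
  if (!is.null(cb))
    prof$color_mean <- vapply(idx, function(i) mean(cb[i]), 0)
  rownames(prof) <- NULL
  structure(prof, class = c("dependence_profile", "data.frame"),
            feature = feature, color_by = color_by,
            raw = data.frame(value = x, attribution = a))
}

#' Plot a dependence profile
#'
#' @param x A `dependence_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dependence_profile <- function(x, ...) {
  raw <- attr(x, "raw")
  plot(raw$value, raw$attribution, pch = ".", col = "grey60",
       xlab = attr(x, "feature"), ylab = "attribution (log-odds)", ...)
  graphics::lines(x$center, x$mean_attribution, col = "red3", lwd = 2)
  invisible(x)
}

#' Test a dependence profile for a U-shaped association
#'
#' Declares a U-shape when the mean attribution below `low_edge` and the
#' mean attribution above `high_edge` both exceed the mean attribution
#' inside `mid_band` by more than `margin`. Both tail-vs-middle differences
#' are returned. If either extreme region holds no rows the result is
#' undefined (`NA`, with a warning), not silently false.
#'
#' @param profile A `dependence_profile`.
#' @param low_edge Values strictly below this form the low tail.
#' @param mid_band Length-2 numeric, the closed middle band.
#' @param high_edge Values strictly above this form the high tail.
#' @param margin Required excess of each tail mean over the middle mean.
#' @return List of class `ushape_test`: `ushape` (TRUE/FALSE/NA),
#'   `low_margin`, `high_margin`, per-region means and counts.
#' @export
detect_ushape <- function(profile, low_edge, mid_band, high_edge,
                          margin = 0) {
  stop_if_not(inherits(profile, "dependence_profile"),
              "profile must be a dependence_profile")
  stop_if_not(length(mid_band) == 2L && mid_band[1] <= mid_band[2],
              "mid_band must be an increasing pair")
  raw <- attr(profile, "raw")
  lo <- raw$attribution[raw$value < low_edge]
  mid <- raw$attribution[raw$value >= mid_band[1] & raw$value <= mid_band[2]]
  hi <- raw$attribution[raw$value > high_edge]
  if (!length(lo) || !length(hi) || !length(mid)) {
    warning("empty extreme or middle region: U-shape undefined")
    return(structure(list(ushape = NA, low_margin = NA_real_,
                          high_margin = NA_real_,
                          n = c(low = length(lo), mid = length(mid),
                                high = length(hi))),
                     class = "ushape_test"))
  }
  low_margin <- mean(lo) - mean(mid)
  high_margin <- mean(hi) - mean(mid)
  structure(list(ushape = low_margin > margin && high_margin > margin,
                 low_margin = low_margin, high_margin = high_margin,
                 mean_low = mean(lo), mean_mid = mean(mid),
                 mean_high = mean(hi),
                 n = c(low = length(lo), mid = length(mid),
                       high = length(hi))),
            class = "ushape_test")
}

#' @method print ushape_test
#' @export
print.ushape_test <- function(x, ...) {
  cat(sprintf("U-shape: %s (low tail margin %+.4f, high tail margin %+.4f)\n",
              ifelse(is.na(x$ushape), "undefined", x$ushape),
              x$low_margin, x$high_margin))
  invisible(x)
}
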