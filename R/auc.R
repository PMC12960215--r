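#' ROC curve points
#'
#' Classical ROC construction: thresholds sweep the unique score values in
#' decreasing order; ties are handled by moving along the tied block at
#' once, so the trapezoidal integral of these points equals the tie-averaged
#' rank (Mann–Whitney) AUC.
#'
#' @param scores Numeric predictions (higher = more positive).
#' @param labels 0/1 outcomes.
#' @return data.frame with columns `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1), non-decreasing in both coordinates.
#' @export
roc_points <- function(scores, labels) {
  check_binary(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  keep <- c(s[-length(s)] != s[-1], TRUE)  # end of each tied block
  tp <- cumsum(y == 1)[keep]
  fp <- cumsum(y == 0)[keep]
  data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
}

#' Area under the ROC curve
#'
#' Computed as the tie-corrected rank statistic: the probability that a
#' random positive outranks a random negative, counting ties as 1/2. Equal
#' (to numerical precision) to trapezoidal integration of [roc_points()].
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`. Errors when only one class is present (AUC
#'   undefined), rather than returning NaN silently.
#' @export
auc_rank <- function(scores, labels) {
  check_binary(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)  # average ranks on ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# trapezoidal area under an ROC point set
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

check_binary <- function(labels) {
  stop_if_not(all(labels %in% c(0, 1)), "labels must be 0/1")
  stop_if_not(any(labels == 0) && any(labels == 1),
              "AUC undefined: labels contain a single class")
}

#' Evaluate a fitted dropout model on a test set
#'
#' @param model A `dropout_model`.
#' @param features data.frame or matrix with the model's feature columns.
#' @param labels 0/1 outcomes.
#' @return List of class `model_eval`: `auc`, `roc` (data.frame), `n`,
#'   `n_pos`.
#' @export
evaluate_auc <- function(model, features, labels) {
  s <- predict(model, features, type = "margin")
  structure(list(auc = auc_rank(s, labels), roc = roc_points(s, labels),
                 n = length(labels), n_pos = sum(labels == 1)),
            class = "model_eval")
}

#' @method print model_eval
#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("AUC %.4f on %d rows (%d positive)\n", x$auc, x$n, x$n_pos))
  invisible(x)
}
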