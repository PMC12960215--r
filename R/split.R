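#' Leakage-safe cohort split
#'
#' User-level split mirroring the two-period validation design: every
#' regime-A user (the analogue of the period without push notifications)
#' forms Test 1; an equally sized random sample of regime-B users forms
#' Test 2; all remaining users train the model. Assignment is at the user
#' level, so no user's windows can appear on both sides of the split.
#'
#' @param users data.frame with `user_id` and `regime` (A/B).
#' @param seed Integer seed controlling the Test 2 sample.
#' @return List of class `split_plan`: `train`, `test1`, `test2` (character
#'   vectors of user ids, pairwise disjoint, `|test2| == |test1|`), `seed`.
#' @export
split_cohorts <- function(users, seed = 1L) {
  stop_if_not(all(c("user_id", "regime") %in% names(users)),
              "users must have user_id and regime columns")
  a <- users$user_id[users$regime == "A"]
  b <- users$user_id[users$regime == "B"]
  stop_if_not(length(a) > 0L && length(b) > 0L, "both regimes must be present")
  stop_if_not(length(b) >= length(a),
              "cannot match sizes: fewer regime-B than regime-A users")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  test2 <- sort(sample(b, length(a)))
  structure(list(train = sort(setdiff(b, test2)), test1 = sort(a),
                 test2 = test2, seed = as.integer(seed)),
            class = "split_plan")
}

#' @method print split_plan
#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d train / %d test1 (regime A) / %d test2 (regime B), seed %d\n",
              length(x$train), length(x$test1), length(x$test2), x$seed))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}
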