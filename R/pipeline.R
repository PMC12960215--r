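#' Run the full continuity-analysis pipeline
#'
#' Executes simulate -> label -> featurize -> split/train -> attribute ->
#' describe, writing every artifact as CSV/JSON under `out_dir` together
#' with a run manifest (config, seeds, per-stage row counts, output paths,
#' config hash). Re-running with the same configuration reproduces all
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress per-stage progress messages?
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stop_if_not(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  outputs <- character(0)
  counts <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("stage simulate: %d users", config$generator$n_users)
  cohort <- stage("simulate", simulate_cohort(config$generator))
  outputs <- c(outputs, write_cohort(cohort, out_dir))
  counts$users <- nrow(cohort$users)
  counts$measurements <- nrow(cohort$measurements)

  say("stage label")
  series <- stage("label", build_daily_series(
    cohort$measurements,
    cutoff_day = config$generator$calendar_span_days - 1L))
  windows <- stage("label", label_windows(
    series, x_grid = config$x_grid, window_len = config$window_len,
    threshold = config$inactivity_threshold,
    drop_empty = config$drop_empty_windows))
  wpath <- file.path(out_dir, "windows.csv")
  utils::write.csv(windows, wpath, row.names = FALSE)
  outputs <- c(outputs, windows = wpath)
  counts$windows <- nrow(windows)

  say("stage featurize: %d windows", nrow(windows))
  features <- stage("featurize",
                    build_feature_matrix(series, windows, cohort$users))
  fpath <- file.path(out_dir, "features.csv")
  utils::write.csv(features, fpath, row.names = FALSE)
  outputs <- c(outputs, features = fpath)

  say("stage train: horizons %s", paste(config$x_grid, collapse = ","))
  split <- stage("train", split_cohorts(cohort$users, seed = config$seed))
  sweep <- stage("train", horizon_sweep(
    features, windows, split, x_grid = config$x_grid,
    model_types = config$model_types, n_folds = config$n_folds,
    budget_trials = config$budget_trials, seed = config$seed))
  rpath <- file.path(out_dir, "model_report.json")
  jsonlite::write_json(sweep$report, rpath, digits = NA, dataframe = "rows")
  outputs <- c(outputs, model_report = rpath)
  for (key in names(sweep$rocs)) {
    p <- file.path(out_dir, paste0("roc_", key, ".csv"))
    utils::write.csv(sweep$rocs[[key]], p, row.names = FALSE)
    outputs <- c(outputs, p)
  }

  say("stage explain: horizon %d", config$shap_horizon)
  key <- paste0(config$model_types[1], "_", config$shap_horizon)
  model <- sweep$models[[key]]
  ycol <- paste0("y_", config$shap_horizon)
  eval_rows <- windows$user_id %in% split$test2 & !is.na(windows[[ycol]])
  report <- stage("explain",
                  compute_attributions(model,
                                       features[eval_rows, , drop = FALSE]))
  rk <- rank_features(report)
  kpath <- file.path(out_dir, "ranking.csv")
  utils::write.csv(rk, kpath, row.names = FALSE)
  outputs <- c(outputs, ranking = kpath)
  for (feat in c("age_years", "sbp_max")) {
    prof <- dependence_profile(report, feat)
    p <- file.path(out_dir, paste0("dependence_", feat, ".csv"))
    utils::write.csv(as.data.frame(prof), p, row.names = FALSE)
    outputs <- c(outputs, p)
  }
  counts$explained_rows <- nrow(report$attributions)

  say("stage describe")
  gaps <- stage("describe",
                do.call(rbind, lapply(series, detect_gaps)))
  nr <- non_resumption_curve(gaps)
  ev <- dropout_events(series)
  prof_users <- cohort$users[match(ev$user_id, cohort$users$user_id), ]
  ci <- cumulative_incidence(ev$time, ev$event, prof_users$sex)
  age <- age_at_day(prof_users$birth_ym, ev$first_day)
  isA <- prof_users$regime == "A"
  std <- standardized_incidence_comparison(
    data.frame(time = ev$time[isA], event = ev$event[isA],
               age = age[isA], sex = prof_users$sex[isA]),
    data.frame(time = ev$time[!isA], event = ev$event[!isA],
               age = age[!isA], sex = prof_users$sex[!isA]))
  monthly <- monthly_dropout_rate(series)
  age_rates <- dropout_rate_by_age(cohort$users, series,
                                   threshold = config$inactivity_threshold)
  wk <- do.call(rbind, lapply(c("all", "weekday", "weekend"), function(sc)
    compare_week_delta_by_outcome(features, windows[[ycol]], sc)))
  desc <- list(nonresumption_curve = nr, age_dropout_rates = age_rates,
               cumulative_incidence_by_sex = ci,
               standardized_A = std$A, standardized_B = std$B,
               monthly_dropout = monthly, week_delta_tests = wk)
  for (nm in names(desc)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(desc[[nm]]), p, row.names = FALSE)
    outputs <- c(outputs, p)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bpdropout")),
    config = unclass_config(config),
    config_hash = config_hash(config),
    seeds = list(generator = config$generator$seed, pipeline = config$seed),
    row_counts = counts,
    outputs = unname(outputs),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  missing_out <- outputs[!file.exists(outputs) | file.size(outputs) == 0]
  stop_if_not(length(missing_out) == 0, "missing or empty outputs: ",
              paste(missing_out, collapse = ", "))
  invisible(manifest)
}

# per-user first-dropout event table for the incidence analyses
dropout_events <- function(series_list, threshold = 28L) {
  do.call(rbind, lapply(series_list, function(s) {
    onset <- first_inactive_onset(s, threshold)
    data.frame(user_id = s$user_id, first_day = s$first_day,
               time = if (is.na(onset)) s$cutoff_day - s$first_day
                      else onset - s$first_day,
               event = as.integer(!is.na(onset)),
               stringsAsFactors = FALSE)
  }))
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$generator <- unclass(cfg$generator)
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_config(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
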