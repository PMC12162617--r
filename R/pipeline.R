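# End-to-end orchestration: ingest or simulate a cohort, score sleep, cut
# settling periods, extract window features, classify, and summarize feature
# importance and group statistics in one reproducible report.

#' Pipeline configuration
#'
#' Exactly one of `synthetic` (a [cohort_config()]) or `data_dir` (a
#' directory holding one epoch CSV per child plus `diary.csv` and
#' `labels.csv`) must be supplied.
#'
#' @param synthetic a [cohort_config()] for simulated input, or `NULL`.
#' @param data_dir directory of on-disk input files, or `NULL`.
#' @param sleep_scoring named list of [score_nights()] parameters.
#' @param extraction named list: `mode` (`"diary"` or `"fixed_offset"`),
#'   `fixed_offset_min`, `min_duration`, `min_nights`.
#' @param window_min,stride_min rolling-window specification for the main
#'   classification run.
#' @param rf an [rf_params()] object, or `NULL` to select parameters by grid
#'   search on a stratified 4:1 training split (the selected set is then
#'   frozen for the k-fold run).
#' @param grid hyperparameter grid for the search (see
#'   [grid_search_params()]).
#' @param k cross-validation folds.
#' @param fold_mode `"paper"` or `"grouped"`, see [stratified_folds()].
#' @param sweep `NULL` to skip the window/stride sweep, or a list with
#'   `windows` and `strides`.
#' @param importance_repeats permutation-importance repeats (0 skips the
#'   stage).
#' @param seed single pipeline seed; every stage derives its randomness from
#'   it.
#' @param output_dir directory for persisted stage artifacts (`NULL` keeps
#'   everything in memory).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = cohort_config(), data_dir = NULL,
                            sleep_scoring = list(),
                            extraction = list(),
                            window_min = 11, stride_min = 1,
                            rf = rf_params(), grid = NULL,
                            k = 10, fold_mode = "paper",
                            sweep = NULL, importance_repeats = 10,
                            seed = 1L, output_dir = NULL) {
  if (is.null(synthetic) == is.null(data_dir)) {
    stop_settledown("provide exactly one of `synthetic` or `data_dir`",
                    "settledown_config_error")
  }
  ss_defaults <- list(onset_run = 5, offset_run = 10, min_rest_minutes = 160,
                      onset_consecutive = 3, reconcile_threshold_min = 30)
  ex_defaults <- list(mode = "diary", fixed_offset_min = 60, min_duration = 3,
                      min_nights = 4)
  structure(
    list(synthetic = synthetic, data_dir = data_dir,
         sleep_scoring = utils::modifyList(ss_defaults, sleep_scoring),
         extraction = utils::modifyList(ex_defaults, extraction),
         window_min = window_min, stride_min = stride_min,
         rf = rf, grid = grid, k = k, fold_mode = fold_mode, sweep = sweep,
         importance_repeats = importance_repeats,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' `synthetic` and `rf` sub-maps are passed to [cohort_config()] /
#' [rf_params()]. Group parameters may be overridden under
#' `synthetic: group_params: SS:`/`NSS:`.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic)) {
    sy <- y$synthetic
    if (!is.null(sy$group_params)) {
      sy$group_params <- list(
        SS = do.call(group_params, sy$group_params$SS),
        NSS = do.call(group_params, sy$group_params$NSS)
      )
    }
    if (!is.null(sy$nights_range)) sy$nights_range <- unlist(sy$nights_range)
    args$synthetic <- do.call(cohort_config, sy)
  } else {
    args$synthetic <- NULL
  }
  if (!is.null(y$data_dir)) args$data_dir <- y$data_dir
  if (!is.null(y$rf)) {
    if (!is.null(y$rf$max_depth) && identical(y$rf$max_depth, "unlimited")) {
      y$rf$max_depth <- Inf
    }
    args$rf <- do.call(rf_params, y$rf)
  }
  for (key in c("sleep_scoring", "extraction", "window_min", "stride_min",
                "k", "fold_mode", "sweep", "importance_repeats", "seed",
                "output_dir")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  do.call(pipeline_config, args)
}

#' Read an on-disk cohort
#'
#' @param dir directory containing per-child epoch CSVs plus `diary.csv` and
#'   `labels.csv` (the [write_cohort()] layout).
#' @return a `cohort_dataset`.
#' @export
read_cohort_dir <- function(dir) {
  labels <- read_labels_csv(file.path(dir, "labels.csv"))
  diary <- read_diary_csv(file.path(dir, "diary.csv"))
  series <- lapply(labels$child_id, function(id) {
    read_epoch_csv(file.path(dir, paste0(id, ".csv")), child_id = id)
  })
  assemble_dataset(series, diary, labels)
}

#' Run the full settling-down analysis pipeline
#'
#' Stages: data ingestion or simulation, Sadeh/rest-period scoring, settling
#' extraction with inclusion rules, rolling-window features, (optional) grid
#' search and window/stride sweep, stratified k-fold random-forest
#' cross-validation with Youden thresholds, permutation importance, subject
#' aggregates with Mann-Whitney group tests, and the post-hoc standardized
#' regressions. The same configuration and seed always reproduce the same
#' report.
#'
#' @param config a [pipeline_config()].
#' @return object of class `settling_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 5L)
  cohort <- NULL
  if (!is.null(config$synthetic)) {
    cc <- config$synthetic
    cc$seed <- seeds[1L]
    cohort <- generate_cohort(cc)
    dataset <- as_cohort_dataset(cohort)
  } else {
    dataset <- read_cohort_dir(config$data_dir)
  }

  sc <- config$sleep_scoring
  nights <- score_nights(dataset, sc$onset_run, sc$offset_run,
                         sc$min_rest_minutes, sc$onset_consecutive,
                         sc$reconcile_threshold_min)

  ex <- config$extraction
  extracted <- extract_all_settling(dataset, nights, mode = ex$mode,
                                    fixed_offset_min = ex$fixed_offset_min,
                                    min_duration = ex$min_duration)
  included <- apply_inclusion(extracted$periods, ex$min_nights)
  periods <- included$periods
  if (length(periods) == 0L) {
    stop_settledown("no settling periods survive inclusion",
                    "settledown_pipeline_error")
  }

  durations <- settling_duration_summary(periods)
  g_of <- function(tab) {
    ss <- tab[tab$group == "SS", ]
    nss <- tab[tab$group == "NSS", ]
    if (nrow(ss) == 0L || nrow(nss) == 0L) return(NA_real_)
    hedges_g(ss$mean_min, ss$sd_min, ss$n, nss$mean_min, nss$sd_min, nss$n)
  }
  hedges <- c(per_subject = g_of(durations$per_subject),
              per_night = g_of(durations$per_night))

  features <- build_feature_table(periods, config$window_min,
                                  config$stride_min)
  if (length(unique(features$group)) < 2L) {
    stop_settledown("classification needs windows from both groups",
                    "settledown_single_class_error")
  }

  params <- config$rf
  grid_result <- NULL
  if (is.null(params)) {
    split <- train_test_split(features$group, 0.8, seeds[2L])
    train_rows <- features[split$train, ]
    attr(train_rows, "window_min") <- config$window_min
    attr(train_rows, "stride_min") <- config$stride_min
    params <- if (is.null(config$grid)) {
      grid_search_params(train_rows, seed = seeds[2L],
                         fold_mode = config$fold_mode)
    } else {
      grid_search_params(train_rows, grid = config$grid, seed = seeds[2L],
                         fold_mode = config$fold_mode)
    }
    grid_result <- attr(params, "grid")
  }

  cv <- run_cv(features, params, config$k, config$fold_mode, seeds[3L])

  sweep <- NULL
  if (!is.null(config$sweep)) {
    sweep <- sweep_window_stride(periods, config$sweep$windows,
                                 config$sweep$strides, params, config$k,
                                 config$fold_mode, seeds[4L])
  }

  importance <- NULL
  if (config$importance_repeats > 0) {
    importance <- permutation_importance(features, params,
                                         config$importance_repeats,
                                         seed = seeds[5L])
  }

  aggregates <- subject_aggregates(features, periods, dataset$labels)
  tests <- group_tests(aggregates)
  regressions <- posthoc_regression_table(aggregates)

  report <- structure(
    list(config = config, cohort = cohort,
         n_children = length(unique(periods_df(periods)$child_id)),
         n_periods = length(periods),
         excluded_children = included$excluded,
         rejections = extracted$rejections,
         durations = durations, hedges_g = hedges,
         features_n = nrow(features), params = params,
         grid_result = grid_result, cv = cv, sweep = sweep,
         importance = importance, aggregates = aggregates,
         group_tests = tests, regressions = regressions,
         seed = config$seed),
    class = "settling_report"
  )
  if (!is.null(config$output_dir)) {
    persist_report(report, features, config$output_dir)
  }
  report
}

# Persist stage artifacts as plain CSV plus a JSON manifest so a run can be
# audited or partially rerun.
persist_report <- function(report, features, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(report$config, force = TRUE, auto_unbox = TRUE)
  cfg_file <- file.path(dir, "config.json")
  writeLines(cfg_json, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  write_artifact <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(sprintf("# settledown config %s seed %d", cfg_hash,
                       report$seed), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  ft <- features
  ft$window_start <- format_ts(ft$window_start)
  write_artifact(ft, "features.csv")
  write_artifact(report$cv$folds, "cv_report.csv")
  if (!is.null(report$sweep)) write_artifact(report$sweep, "sweep.csv")
  if (!is.null(report$importance)) {
    write_artifact(report$importance, "importance.csv")
  }
  write_artifact(report$aggregates, "subject_aggregates.csv")
  write_artifact(report$group_tests, "group_tests.csv")
  reg <- do.call(rbind, lapply(report$regressions, function(r) {
    pred <- setdiff(r$coefficients$term, c("group", "age_years", "sex"))
    data.frame(model = r$model_id,
               beta_group = r$coefficients$beta_std[r$coefficients$term == "group"],
               beta_predictor = if (length(pred)) {
                 r$coefficients$beta_std[r$coefficients$term == pred]
               } else NA_real_,
               constant = r$constant[["estimate"]],
               r_squared = r$r_squared, f_stat = r$f_stat,
               f_pvalue = r$f_pvalue, n = r$n_obs)
  }))
  write_artifact(reg, "regressions.csv")
  durations <- rbind(cbind(framing = "per_subject",
                           report$durations$per_subject),
                     cbind(framing = "per_night", report$durations$per_night))
  write_artifact(durations, "duration_summary.csv")
  manifest <- list(config_hash = cfg_hash, seed = report$seed,
                   version = as.character(utils::packageVersion("settledown")),
                   n_children = report$n_children,
                   n_periods = report$n_periods,
                   n_windows = report$features_n)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.settling_report <- function(x, ...) {
  cat("== settling-down analysis report ==\n")
  cat(sprintf("children included: %d; settling periods: %d; windows: %d (W=%d, S=%d)\n",
              x$n_children, x$n_periods, x$features_n, x$config$window_min,
              x$config$stride_min))
  ds <- x$durations$per_subject
  for (i in seq_len(nrow(ds))) {
    cat(sprintf("  %s settling duration (per-subject): %.2f min (SD %.2f, n=%d)\n",
                ds$group[i], ds$mean_min[i], ds$sd_min[i], ds$n[i]))
  }
  cat(sprintf("  Hedges' g (per-subject means): %.2f\n",
              x$hedges_g[["per_subject"]]))
  avg <- x$cv$average
  cat(sprintf("cross-validation (%d-fold, %s): accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              x$config$k, x$config$fold_mode, avg[["accuracy"]],
              avg[["sensitivity"]], avg[["specificity"]], avg[["auc"]]))
  if (!is.null(x$sweep)) {
    best <- x$sweep[x$sweep$best, ]
    cat(sprintf("sweep best cell: window %d / stride %d (AUC %.3f)\n",
                best$window_min[1L], best$stride_min[1L], best$mean_auc[1L]))
  }
  if (!is.null(x$importance)) {
    cat(sprintf("most important feature: %s (AUC decrease %.3f)\n",
                x$importance$feature[1L], x$importance$mean_auc_decrease[1L]))
  }
  invisible(x)
}

#' @export
summary.settling_report <- function(object, ...) {
  print(object)
  cat("\nGroup tests (Mann-Whitney):\n")
  print(object$group_tests, row.names = FALSE, digits = 3)
  cat("\nRegressions (standardized betas):\n")
  for (r in object$regressions) print(r)
  invisible(object)
}
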