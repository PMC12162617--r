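# Random-forest classification of settling-down windows (SS vs NSS) with
# stratified 10-fold cross-validation, Youden-J decision thresholds and the
# window/stride sweep. SS is always the positive class. Forest scores are
# vote fractions: the share of trees voting SS for a window.

POSITIVE_CLASS <- "SS"

#' Random-forest hyperparameters
#'
#' @param n_trees number of trees (>= 1).
#' @param max_depth maximum tree depth; `Inf` grows unlimited trees.
#' @param seed integer seed used for every forest fit.
#' @return list of class `rf_params`.
#' @export
rf_params <- function(n_trees = 200, max_depth = Inf, seed = 1L) {
  assert_scalar_number(n_trees, "n_trees", min = 1)
  if (!(is.numeric(max_depth) && length(max_depth) == 1L &&
        (is.infinite(max_depth) || max_depth >= 1))) {
    stop_settledown("max_depth must be >= 1 or Inf", "settledown_config_error")
  }
  structure(list(n_trees = as.integer(n_trees), max_depth = max_depth,
                 seed = as.integer(seed)), class = "rf_params")
}

rf_fit <- function(x, y, params) {
  ranger::ranger(
    x = x, y = y, num.trees = params$n_trees,
    max.depth = if (is.finite(params$max_depth)) params$max_depth else 0,
    seed = params$seed, num.threads = 1L
  )
}

# Vote-fraction scores for the positive class.
rf_scores <- function(fit, x) {
  pred <- stats::predict(fit, data = x, predict.all = TRUE,
                         num.threads = 1L)$predictions
  pos <- match(POSITIVE_CLASS, fit$forest$levels)
  rowMeans(pred == pos)
}

#' Area under the ROC curve from scores
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling; invariant to any
#' strictly monotone transform of the scores.
#'
#' @param positive logical vector, `TRUE` for positive-class rows.
#' @param scores numeric classifier scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(positive, scores) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-J optimal decision threshold
#'
#' Maximizes `J = TPR - FPR` over the finite candidate set of thresholds: the
#' midpoints between adjacent distinct sorted scores plus `-Inf` and `+Inf`
#' (a row is called positive when its score is `>=` the threshold). Ties are
#' broken toward the lowest threshold.
#'
#' @inheritParams auc_score
#' @return the selected threshold.
#' @export
youden_threshold <- function(positive, scores) {
  if (sum(positive) == 0L || sum(!positive) == 0L) {
    stop_settledown("need at least one positive and one negative label",
                    "settledown_argument_error")
  }
  u <- sort(unique(scores))
  cands <- c(-Inf, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, Inf)
  j <- vapply(cands, function(t) {
    pred <- scores >= t
    sum(pred & positive) / sum(positive) - sum(pred & !positive) / sum(!positive)
  }, numeric(1))
  cands[which(j >= max(j) - 1e-12)[1L]]
}

threshold_metrics <- function(positive, scores, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & positive); fn <- sum(!pred & positive)
  tn <- sum(!pred & !positive); fp <- sum(pred & !positive)
  c(accuracy = (tp + tn) / length(positive),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Stratified cross-validation folds
#'
#' `mode = "paper"` deals each subject's windows round-robin across the k
#' folds, which keeps the label ratio of every fold close to the global ratio
#' while balancing subjects over folds; windows from one subject then appear
#' in both train and test sets of a fold. `mode = "grouped"` instead assigns
#' every subject's windows to a single fold (stratified by label at the
#' subject level), the leakage-safe alternative.
#'
#' @param labels character/factor window labels.
#' @param subjects character subject id per window.
#' @param k number of folds.
#' @param mode `"paper"` or `"grouped"`.
#' @param seed integer seed for the shuffles.
#' @return list of `k` lists with integer `train` and `test` indices; test
#'   sets are disjoint and cover all rows.
#' @export
stratified_folds <- function(labels, subjects, k = 10,
                             mode = c("paper", "grouped"), seed = 1L) {
  mode <- match.arg(mode)
  n <- length(labels)
  if (k > n) {
    stop_settledown("k exceeds the number of rows",
                    "settledown_argument_error")
  }
  fold_of <- integer(n)
  if (mode == "paper") {
    # label-major dealing: within each label, subjects are visited in random
    # order and their shuffled windows dealt round-robin with a pointer that
    # persists across subjects. Each fold then holds each label's windows to
    # within one, so fold label ratios track the global ratio, while every
    # subject's windows are spread across folds.
    with_seed(seed, {
      for (g in unique(labels)) {
        subj_g <- unique(subjects[labels == g])
        subj_g <- subj_g[sample.int(length(subj_g))]
        ptr <- sample.int(k, 1L) - 1L
        for (s in subj_g) {
          idx <- which(subjects == s & labels == g)
          idx <- idx[sample.int(length(idx))]
          fold_of[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
          ptr <- ptr + length(idx)
        }
      }
    })
  } else {
    with_seed(seed, {
      subj <- unique(subjects)
      subj_lab <- labels[match(subj, subjects)]
      assign_fold <- integer(length(subj))
      offset <- 0L
      for (g in unique(subj_lab)) {
        ids <- which(subj_lab == g)
        ids <- ids[sample.int(length(ids))]
        assign_fold[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
        offset <- offset + length(ids)
      }
      fold_of <- assign_fold[match(subjects, subj)]
    })
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Stratified train/test split
#'
#' Splits window rows into train and test sets at the given ratio,
#' stratifying by label (used for the 4:1 hyperparameter-search split and the
#' permutation-importance hold-out).
#'
#' @param labels window labels.
#' @param train_frac fraction of rows per label assigned to training
#'   (default 0.8, a 4:1 split).
#' @param seed integer seed.
#' @return list with integer `train` and `test` indices.
#' @export
train_test_split <- function(labels, train_frac = 0.8, seed = 1L) {
  with_seed(seed, {
    train <- integer(0)
    for (g in unique(labels)) {
      idx <- which(labels == g)
      train <- c(train, sample(idx, round(train_frac * length(idx))))
    }
    list(train = sort(train), test = setdiff(seq_along(labels), train))
  })
}

cv_mean_auc <- function(x, y, subjects, params, k, fold_mode, seed) {
  folds <- stratified_folds(as.character(y), subjects, k, fold_mode, seed)
  aucs <- vapply(folds, function(f) {
    ytr <- y[f$train]
    if (length(unique(ytr)) < 2L) return(NA_real_)
    fit <- rf_fit(x[f$train, , drop = FALSE], ytr, params)
    auc_score(y[f$test] == POSITIVE_CLASS,
              rf_scores(fit, x[f$test, , drop = FALSE]))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Grid search for forest hyperparameters
#'
#' Evaluates every (n_trees, max_depth) cell by inner cross-validated AUC on
#' the training split and returns the best cell; ties are broken toward fewer
#' trees, then shallower depth, so the selection is deterministic.
#'
#' @param features a window feature table (training rows only).
#' @param grid data frame with columns `n_trees` and `max_depth` (`Inf` for
#'   unlimited). Default: 100/200/500 trees by depth 3/5/10/unlimited.
#' @param inner_folds number of inner CV folds.
#' @param fold_mode fold construction mode, see [stratified_folds()].
#' @param seed integer seed.
#' @return the selected [rf_params()], with the evaluated grid (and its AUCs)
#'   in attribute `grid`.
#' @export
grid_search_params <- function(features,
                               grid = expand.grid(n_trees = c(100, 200, 500),
                                                  max_depth = c(3, 5, 10, Inf)),
                               inner_folds = 5, fold_mode = "paper",
                               seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0L) {
    stop_settledown("empty hyperparameter grid", "settledown_argument_error")
  }
  x <- features[, feature_names()]
  y <- factor(features$group, levels = c("NSS", "SS"))
  seeds <- derive_seeds(seed, nrow(grid) + 1L)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    cv_mean_auc(x, y, features$child_id,
                rf_params(grid$n_trees[i], grid$max_depth[i], seeds[i]),
                inner_folds, fold_mode, seeds[nrow(grid) + 1L])
  }, numeric(1))
  best <- which(grid$auc >= max(grid$auc) - 1e-12)
  best <- best[order(grid$n_trees[best], grid$max_depth[best])][1L]
  out <- rf_params(grid$n_trees[best], grid$max_depth[best], seed)
  attr(out, "grid") <- grid
  out
}

#' Cross-validated random-forest classification of windows
#'
#' For each stratified fold: fits a forest on the training rows, picks the
#' decision threshold maximizing Youden's J on the *training* scores, then
#' reports test-fold AUC (from vote fractions) and accuracy / sensitivity /
#' specificity at that threshold. SS is the positive class, so sensitivity is
#' the rate at which SS windows are recognized.
#'
#' @param features a window feature table from [build_feature_table()].
#' @param params an [rf_params()] object.
#' @param k number of folds.
#' @param fold_mode see [stratified_folds()].
#' @param seed integer seed controlling fold assignment and per-fold fits.
#' @return object of class `settling_cv`: list with `folds` (per-fold metric
#'   data frame), `average` (named means over folds), `params`, `fold_mode`,
#'   `window_min`/`stride_min` and `seed`.
#' @export
run_cv <- function(features, params = rf_params(), k = 10,
                   fold_mode = c("paper", "grouped"), seed = 1L) {
  fold_mode <- match.arg(fold_mode)
  if (nrow(features) == 0L) {
    stop_settledown("empty feature table", "settledown_argument_error")
  }
  y <- factor(features$group, levels = c("NSS", "SS"))
  if (length(unique(features$group)) < 2L) {
    stop_settledown("both classes must be present for classification",
                    "settledown_single_class_error")
  }
  x <- features[, feature_names()]
  seeds <- derive_seeds(seed, k + 1L)
  folds <- stratified_folds(as.character(y), features$child_id, k, fold_mode,
                            seeds[k + 1L])
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    if (length(unique(y[tr])) < 2L || length(te) == 0L) {
      warning(sprintf("fold %d skipped: single-class training data", f))
      next
    }
    fit <- rf_fit(x[tr, , drop = FALSE], y[tr],
                  rf_params(params$n_trees, params$max_depth, seeds[f]))
    thr <- youden_threshold(y[tr] == POSITIVE_CLASS,
                            rf_scores(fit, x[tr, , drop = FALSE]))
    sc <- rf_scores(fit, x[te, , drop = FALSE])
    met <- threshold_metrics(y[te] == POSITIVE_CLASS, sc, thr)
    rows[[f]] <- data.frame(fold = f, accuracy = met["accuracy"],
                            sensitivity = met["sensitivity"],
                            specificity = met["specificity"],
                            auc = auc_score(y[te] == POSITIVE_CLASS, sc),
                            threshold = thr, row.names = NULL)
  }
  folds_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(
    list(folds = folds_df,
         average = colMeans(folds_df[, c("accuracy", "sensitivity",
                                         "specificity", "auc")],
                            na.rm = TRUE),
         params = params, fold_mode = fold_mode,
         window_min = attr(features, "window_min"),
         stride_min = attr(features, "stride_min"), seed = seed),
    class = "settling_cv"
  )
}

#' @export
print.settling_cv <- function(x, digits = 3, ...) {
  cat(sprintf("<settling_cv> %d-fold (%s mode), %d trees, depth %s\n",
              nrow(x$folds), x$fold_mode, x$params$n_trees,
              ifelse(is.finite(x$params$max_depth),
                     as.character(x$params$max_depth), "unlimited")))
  if (!is.null(x$window_min)) {
    cat(sprintf("  window %d min, stride %d min\n", x$window_min,
                x$stride_min))
  }
  avg <- round(x$average, digits)
  cat(sprintf("  average: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              avg["accuracy"], avg["sensitivity"], avg["specificity"],
              avg["auc"]))
  invisible(x)
}

#' @export
summary.settling_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold metrics:\n")
  print(object$folds, row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
plot.settling_cv <- function(x, ...) {
  m <- t(as.matrix(x$folds[, c("accuracy", "sensitivity", "specificity",
                               "auc")]))
  graphics::barplot(m, beside = TRUE, names.arg = x$folds$fold,
                    xlab = "fold", ylim = c(0, 1),
                    legend.text = rownames(m),
                    args.legend = list(x = "bottomright", bty = "n"), ...)
  invisible(x)
}

#' Window/stride grid sweep
#'
#' Rebuilds the feature table and runs the cross-validation for every
#' (window, stride) cell, recording the mean AUC; the best cell is flagged.
#' Cells where no period is long enough to yield a window are recorded with
#' `NA` AUC.
#'
#' @param periods included settling periods.
#' @param windows,strides grid of window lengths and strides in minutes
#'   (default 7/9/11/13 by 1/3).
#' @param params an [rf_params()].
#' @param k folds per cell.
#' @param fold_mode see [stratified_folds()].
#' @param seed integer seed.
#' @return object of class `settling_sweep`: data frame with one row per grid
#'   cell (`window_min`, `stride_min`, `n_windows`, `mean_auc`, `best`).
#' @export
sweep_window_stride <- function(periods, windows = c(7, 9, 11, 13),
                                strides = c(1, 3), params = rf_params(),
                                k = 10, fold_mode = "paper", seed = 1L) {
  grid <- expand.grid(window_min = windows, stride_min = strides)
  grid <- grid[order(grid$window_min, grid$stride_min), ]
  rownames(grid) <- NULL
  grid$n_windows <- NA_integer_
  grid$mean_auc <- NA_real_
  seeds <- derive_seeds(seed, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ft <- build_feature_table(periods, grid$window_min[i], grid$stride_min[i])
    grid$n_windows[i] <- nrow(ft)
    if (nrow(ft) == 0L || length(unique(ft$group)) < 2L) next
    cv <- run_cv(ft, params, k, fold_mode, seeds[i])
    grid$mean_auc[i] <- cv$average[["auc"]]
  }
  grid$best <- !is.na(grid$mean_auc) &
    grid$mean_auc == max(grid$mean_auc, na.rm = TRUE)
  class(grid) <- c("settling_sweep", "data.frame")
  grid
}

#' @export
print.settling_sweep <- function(x, ...) {
  cat("<settling_sweep> mean cross-validated AUC by window/stride\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
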