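# Permutation feature importance, subject-level aggregation, Mann-Whitney
# group comparisons and the post-hoc standardized regressions.

#' Permutation feature importance by AUC decrease
#'
#' On a stratified 4:1 train/hold-out split: fits a baseline forest and
#' records its hold-out AUC; then, for every feature, repeats `n_repeats`
#' times \{permute that feature's training column, refit the forest from
#' scratch, re-evaluate hold-out AUC\}. A feature's importance is the
#' baseline AUC minus the mean permuted AUC; larger decreases mean more
#' informative features.
#'
#' @param features window feature table from [build_feature_table()].
#' @param params an [rf_params()].
#' @param n_repeats permutations per feature.
#' @param train_frac training fraction of the split.
#' @param seed integer seed.
#' @return object of class `settling_importance`: data frame with one row per
#'   feature (`feature`, `mean_auc_decrease`, `sd_auc_decrease`, `n_repeats`),
#'   sorted by decreasing importance, with the baseline AUC in attribute
#'   `baseline_auc`.
#' @export
permutation_importance <- function(features, params = rf_params(),
                                   n_repeats = 10, train_frac = 0.8,
                                   seed = 1L) {
  if (nrow(features) == 0L) {
    stop_settledown("empty feature table", "settledown_argument_error")
  }
  fn <- feature_names()
  y <- factor(features$group, levels = c("NSS", "SS"))
  x <- features[, fn]
  seeds <- derive_seeds(seed, 2L + length(fn) * n_repeats)
  split <- train_test_split(as.character(y), train_frac, seeds[1L])
  xtr <- x[split$train, , drop = FALSE]
  ytr <- y[split$train]
  xte <- x[split$test, , drop = FALSE]
  pos_te <- y[split$test] == POSITIVE_CLASS
  base_fit <- rf_fit(xtr, ytr, rf_params(params$n_trees, params$max_depth,
                                         seeds[2L]))
  baseline <- auc_score(pos_te, rf_scores(base_fit, xte))
  rows <- vector("list", length(fn))
  s <- 2L
  for (i in seq_along(fn)) {
    dec <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      s <- s + 1L
      xp <- xtr
      xp[[fn[i]]] <- with_seed(seeds[s], sample(xp[[fn[i]]]))
      fit <- rf_fit(xp, ytr, rf_params(params$n_trees, params$max_depth,
                                       seeds[s]))
      dec[r] <- baseline - auc_score(pos_te, rf_scores(fit, xte))
    }
    rows[[i]] <- data.frame(feature = fn[i], mean_auc_decrease = mean(dec),
                            sd_auc_decrease = stats::sd(dec),
                            n_repeats = n_repeats, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_auc_decrease), ]
  rownames(out) <- NULL
  attr(out, "baseline_auc") <- baseline
  class(out) <- c("settling_importance", "data.frame")
  out
}

#' @export
print.settling_importance <- function(x, ...) {
  cat(sprintf("<settling_importance> hold-out AUC decrease (baseline %.3f)\n",
              attr(x, "baseline_auc")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.settling_importance <- function(x, ...) {
  graphics::barplot(rev(x$mean_auc_decrease), names.arg = rev(x$feature),
                    horiz = TRUE, las = 1, xlab = "mean AUC decrease", ...)
  invisible(x)
}

#' Subject-level aggregates of settling activity
#'
#' Per included child: the mean of window mean magnitude over all windows
#' (`mean_magnitude`), the mean over nights of the per-night maximum window
#' magnitude (`mean_max_magnitude`), the median window entropy
#' (`median_entropy`), and the mean and SD of nightly settling durations.
#'
#' @param features window feature table.
#' @param periods the settling periods the table was built from.
#' @param labels child-record data frame (for group, age, sex).
#' @return data frame with one row per child that has at least one window;
#'   children with zero windows are dropped (listed in attribute `dropped`).
#' @export
subject_aggregates <- function(features, periods, labels) {
  pdf <- periods_df(periods)
  ids <- intersect(unique(pdf$child_id), unique(features$child_id))
  dropped <- setdiff(unique(pdf$child_id), ids)
  rows <- lapply(ids, function(id) {
    f <- features[features$child_id == id, ]
    p <- pdf[pdf$child_id == id, ]
    night_max <- tapply(f$max_mag, as.character(f$night_date), max)
    lab <- labels[labels$child_id == id, ]
    data.frame(child_id = id, group = lab$group, age_years = lab$age_years,
               sex = lab$sex,
               mean_settling_min = mean(p$duration_min),
               sd_settling_min = stats::sd(p$duration_min),
               mean_magnitude = mean(f$mean_mag),
               mean_max_magnitude = mean(night_max),
               median_entropy = stats::median(f$entropy_bits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  out
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' `U` counts the pairs with `x > y` plus half the tied pairs. The z statistic
#' is `(U - n1 n2 / 2) / sigma_U` with the tie-corrected standard deviation,
#' and the two-sided p-value comes from the normal approximation. Both `U`
#' and the signed `z` are reported.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `z`, `p_value`, `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 3), c(2, 4))$U  # 1 pair with x > y
#' @export
mann_whitney <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) {
    stop_settledown("both samples must be non-empty",
                    "settledown_argument_error")
  }
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  var_u <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (var_u <= 0) {
    stop_settledown("all values identical; U variance is zero",
                    "settledown_degenerate_error")
  }
  z <- (u - n1 * n2 / 2) / sqrt(var_u)
  list(U = u, z = z, p_value = 2 * stats::pnorm(-abs(z)), n1 = n1, n2 = n2)
}

#' Group comparisons of subject aggregates
#'
#' Mann-Whitney tests of each subject-level variable between SS and NSS
#' children (SS sample first, so negative z means smaller SS values).
#'
#' @param aggregates output of [subject_aggregates()].
#' @param variables variables to compare.
#' @return data frame with group means/SDs, `U`, `z` and `p_value` per
#'   variable.
#' @export
group_tests <- function(aggregates,
                        variables = c("mean_settling_min", "mean_magnitude",
                                      "mean_max_magnitude", "sd_settling_min",
                                      "median_entropy")) {
  ss <- aggregates[aggregates$group == "SS", ]
  nss <- aggregates[aggregates$group == "NSS", ]
  rows <- lapply(variables, function(v) {
    # a variable that is constant across both groups carries no test
    mw <- tryCatch(mann_whitney(ss[[v]], nss[[v]]),
                   settledown_degenerate_error = function(e) {
                     list(U = NA_real_, z = NA_real_, p_value = NA_real_)
                   })
    data.frame(variable = v,
               ss_mean = mean(ss[[v]]), ss_sd = stats::sd(ss[[v]]),
               nss_mean = mean(nss[[v]]), nss_sd = stats::sd(nss[[v]]),
               U = mw$U, z = mw$z, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Post-hoc standardized regression on mean settling duration
#'
#' Ordinary least squares of each child's mean settling-down duration on the
#' group indicator (SS = 1), one optional activity predictor, child age and
#' sex (F = 0, M = 1). Coefficients are standardized as
#' `beta * sd(predictor) / sd(outcome)` using sample (n-1) SDs; the intercept
#' stays unstandardized.
#'
#' @param aggregates output of [subject_aggregates()].
#' @param predictor `"none"` (group-only model) or one of `mean_magnitude`,
#'   `mean_max_magnitude`, `sd_settling_min`, `median_entropy`.
#' @return object of class `settling_regression`: list with `model_id`,
#'   `coefficients` (data frame with unstandardized estimates, standard
#'   errors and standardized betas), `constant`, `r_squared`, `f_stat`,
#'   `f_pvalue`, `n_obs` and the underlying `lm` fit.
#' @export
posthoc_regression <- function(aggregates,
                               predictor = c("none", "mean_magnitude",
                                             "mean_max_magnitude",
                                             "sd_settling_min",
                                             "median_entropy")) {
  predictor <- match.arg(predictor)
  df <- data.frame(y = aggregates$mean_settling_min,
                   group = as.numeric(aggregates$group == "SS"),
                   age_years = aggregates$age_years,
                   sex = as.numeric(aggregates$sex == "M"))
  terms <- c("group", "age_years", "sex")
  if (predictor != "none") {
    df$pred <- aggregates[[predictor]]
    names(df)[names(df) == "pred"] <- predictor
    terms <- c("group", predictor, "age_years", "sex")
  }
  if (nrow(df) < length(terms) + 2L) {
    stop_settledown("too few subjects for the regression",
                    "settledown_argument_error")
  }
  sds <- vapply(df[terms], stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop_settledown(sprintf("zero-variance design column: %s",
                            terms[sds == 0][1L]),
                    "settledown_singular_error")
  }
  fit <- stats::lm(stats::reformulate(terms, response = "y"), data = df)
  sm <- summary(fit)
  est <- stats::coef(sm)
  coefs <- data.frame(term = rownames(est)[-1L],
                      estimate = est[-1L, "Estimate"],
                      std_error = est[-1L, "Std. Error"],
                      beta_std = est[-1L, "Estimate"] * sds / stats::sd(df$y),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(model_id = if (predictor == "none") "group_only" else predictor,
         coefficients = coefs,
         constant = c(estimate = unname(est[1L, "Estimate"]),
                      std_error = unname(est[1L, "Std. Error"])),
         r_squared = sm$r.squared,
         f_stat = unname(sm$fstatistic["value"]),
         f_pvalue = unname(stats::pf(sm$fstatistic["value"],
                                     sm$fstatistic["numdf"],
                                     sm$fstatistic["dendf"],
                                     lower.tail = FALSE)),
         n_obs = nrow(df), fit = fit),
    class = "settling_regression"
  )
}

#' @export
print.settling_regression <- function(x, ...) {
  cat(sprintf("<settling_regression> model '%s' (n = %d)\n", x$model_id,
              x$n_obs))
  print(x$coefficients, row.names = FALSE, digits = 3)
  cat(sprintf("  constant %.2f (SE %.2f); R^2 = %.3f; F = %.2f, p = %.4g\n",
              x$constant["estimate"], x$constant["std_error"], x$r_squared,
              x$f_stat, x$f_pvalue))
  invisible(x)
}

#' All post-hoc regression models
#'
#' Fits the group-only model plus one model per activity predictor,
#' mirroring a one-column-per-model regression table.
#'
#' @param aggregates output of [subject_aggregates()].
#' @return list of `settling_regression` objects keyed by model id.
#' @export
posthoc_regression_table <- function(aggregates) {
  preds <- c("none", "mean_magnitude", "mean_max_magnitude",
             "sd_settling_min", "median_entropy")
  out <- lapply(preds, function(p) posthoc_regression(aggregates, p))
  names(out) <- vapply(out, `[[`, character(1), "model_id")
  out
}
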