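test_that("Mann-Whitney U matches brute-force pair counting", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mann_whitney(c(1, 3), c(2, 4))$U, 1)
  ident <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$U, 4.5)
  expect_equal(ident$z, 0)
  set.seed(14)
  for (i in 1:60) {
    n1 <- sample(1:12, 1)
    n2 <- sample(1:12, 1)
    x <- sample(0:8, n1, replace = TRUE)  # integer values force ties
    y <- sample(0:8, n2, replace = TRUE)
    if (length(unique(c(x, y))) < 2) next
    mw <- mann_whitney(x, y)
    expect_equal(mw$U, mw_oracle_U(x, y))
    # complementarity: U + U' = n1 * n2
    expect_equal(mw$U + mann_whitney(y, x)$U, n1 * n2)
  }
  expect_error(mann_whitney(rep(1, 5), rep(1, 4)),
               class = "settledown_degenerate_error")
  expect_error(mann_whitney(numeric(0), 1),
               class = "settledown_argument_error")
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(15)
  for (i in 1:20) {
    x <- stats::rnorm(sample(4:12, 1))
    y <- stats::rnorm(sample(4:12, 1), 0.5)
    mw <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(mw$U, unname(ref$statistic))
    expect_equal(mw$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("subject aggregates match hand computation on a crafted fixture", {
  mkft <- function(child_id, night, max_mags, mean_mags, entropies) {
    data.frame(child_id = child_id, night_date = night, group = "SS",
               window_start = as.POSIXct("2021-10-01 21:00:00", tz = "UTC"),
               mean_mag = mean_mags, max_mag = max_mags, kurtosis = 0,
               skewness = 0, entropy_bits = entropies, sd = 0, iqr = 0)
  }
  ft <- rbind(
    mkft("a", as.Date("2021-10-01"), c(100, 300), c(50, 60), c(1, 2)),
    mkft("a", as.Date("2021-10-02"), c(500, 200), c(70, 80), c(3, 0.5))
  )
  periods <- list(
    make_period(rep(1, 40), child_id = "a"),
    make_period(rep(1, 60), child_id = "a",
                night_date = as.Date("2021-10-02"))
  )
  labels <- data.frame(child_id = "a", group = "SS", age_years = 7, sex = "M")
  agg <- subject_aggregates(ft, periods, labels)
  expect_equal(agg$mean_settling_min, 50)
  expect_equal(agg$sd_settling_min, stats::sd(c(40, 60)))
  expect_equal(agg$sd_settling_min, 14.14, tolerance = 1e-2)
  expect_equal(agg$mean_magnitude, mean(c(50, 60, 70, 80)))
  # per-night maxima are 300 and 500; their mean is 400
  expect_equal(agg$mean_max_magnitude, 400)
  expect_equal(agg$median_entropy, stats::median(c(1, 2, 3, 0.5)))
})

test_that("a constant feature has near-zero permutation importance", {
  ft <- toy_feature_table(n_per_group = 60, seed = 31)
  ft$entropy_bits <- 1.5  # constant column: permutation changes nothing
  imp <- permutation_importance(ft, rf_params(40), n_repeats = 5, seed = 2)
  row <- imp[imp$feature == "entropy_bits", ]
  expect_lt(abs(row$mean_auc_decrease), 0.02)
})

test_that("the label-defining feature dominates permutation importance", {
  set.seed(32)
  ft <- toy_feature_table(n_per_group = 80, shift = 0, seed = 32)
  # labels a deterministic function of max_mag only
  ft$max_mag <- stats::rnorm(nrow(ft))
  ft$group <- ifelse(ft$max_mag > 0, "SS", "NSS")
  ft$child_id <- paste0(ft$group, rep(1:8, length.out = nrow(ft)))
  imp <- permutation_importance(ft, rf_params(40), n_repeats = 5, seed = 3)
  expect_equal(imp$feature[1], "max_mag")
  expect_gt(imp$mean_auc_decrease[1], 2 * max(imp$mean_auc_decrease[-1]))
})

test_that("post-hoc regression matches a normal-equations solve", {
  set.seed(33)
  n <- 12
  agg <- data.frame(
    child_id = sprintf("c%02d", 1:n),
    group = rep(c("SS", "NSS"), each = n / 2),
    age_years = stats::runif(n, 6, 10),
    sex = sample(c("M", "F"), n, replace = TRUE),
    mean_settling_min = stats::rnorm(n, 45, 15),
    sd_settling_min = stats::runif(n, 5, 25),
    mean_magnitude = stats::rnorm(n, 2200, 500),
    mean_max_magnitude = stats::rnorm(n, 9000, 2000),
    median_entropy = stats::runif(n, 2, 3.4)
  )
  fit <- posthoc_regression(agg, "mean_magnitude")
  X <- data.frame(group = as.numeric(agg$group == "SS"),
                  mean_magnitude = agg$mean_magnitude,
                  age_years = agg$age_years,
                  sex = as.numeric(agg$sex == "M"))
  ora <- ols_oracle(X, agg$mean_settling_min)
  expect_equal(fit$coefficients$estimate, unname(ora$beta[-1]),
               tolerance = 1e-9)
  expect_equal(fit$constant[["estimate"]], unname(ora$beta[1]),
               tolerance = 1e-9)
  expect_equal(fit$r_squared, ora$r_squared, tolerance = 1e-9)
  expect_equal(fit$f_stat, ora$f, tolerance = 1e-9)
  expect_equal(fit$n_obs, n)
  # standardized betas rescale by sd(x) / sd(y)
  expect_equal(
    fit$coefficients$beta_std[fit$coefficients$term == "mean_magnitude"],
    unname(ora$beta["mean_magnitude"]) * stats::sd(agg$mean_magnitude) /
      stats::sd(agg$mean_settling_min),
    tolerance = 1e-9)
})

test_that("an exact linear outcome gives beta 1 and R-squared 1", {
  set.seed(34)
  n <- 16
  agg <- data.frame(
    child_id = sprintf("c%02d", 1:n),
    group = rep(c("SS", "NSS"), each = n / 2),
    age_years = stats::runif(n, 6, 10),
    sex = sample(c("M", "F"), n, replace = TRUE),
    median_entropy = stats::runif(n, 2, 3.4)
  )
  agg$mean_settling_min <- 2 * agg$median_entropy
  # lm warns about the (intentional) perfect fit
  fit <- suppressWarnings(posthoc_regression(agg, "median_entropy"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(
    fit$coefficients$beta_std[fit$coefficients$term == "median_entropy"], 1,
    tolerance = 1e-9)
})

test_that("adding a predictor never lowers R-squared", {
  set.seed(35)
  n <- 20
  agg <- data.frame(
    child_id = sprintf("c%02d", 1:n),
    group = rep(c("SS", "NSS"), each = n / 2),
    age_years = stats::runif(n, 6, 10),
    sex = sample(c("M", "F"), n, replace = TRUE),
    mean_settling_min = stats::rnorm(n, 45, 15),
    sd_settling_min = stats::runif(n, 5, 25),
    mean_magnitude = stats::rnorm(n, 2200, 500),
    mean_max_magnitude = stats::rnorm(n, 9000, 2000),
    median_entropy = stats::runif(n, 2, 3.4)
  )
  base <- posthoc_regression(agg, "none")$r_squared
  for (p in c("mean_magnitude", "mean_max_magnitude", "sd_settling_min",
              "median_entropy")) {
    expect_gte(posthoc_regression(agg, p)$r_squared, base - 1e-12)
  }
  agg$sex <- "M"
  expect_error(posthoc_regression(agg, "mean_magnitude"),
               class = "settledown_singular_error")
})
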