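test_that("stratified folds are disjoint, covering and label-balanced", {
  set.seed(9)
  labels <- sample(rep(c("SS", "NSS"), c(60, 40)))
  subjects <- paste0("s", sample(1:10, 100, replace = TRUE))
  folds <- stratified_folds(labels, subjects, k = 10, seed = 1)
  test_idx <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(test_idx), 1:100)
  expect_equal(anyDuplicated(test_idx), 0)
  for (f in folds) {
    expect_setequal(c(f$train, f$test), 1:100)
    ratio <- mean(labels[f$test] == "SS")
    expect_gte(ratio, 0.55)
    expect_lte(ratio, 0.65)
  }
  expect_error(stratified_folds(labels, subjects, k = 200),
               class = "settledown_argument_error")
})

test_that("grouped folds never split a subject across train and test", {
  set.seed(10)
  labels <- rep(c("SS", "NSS"), each = 100)
  subjects <- paste0("s", rep(1:20, each = 10))
  folds <- stratified_folds(labels, subjects, k = 5, mode = "grouped",
                            seed = 2)
  for (f in folds) {
    expect_length(intersect(unique(subjects[f$train]),
                            unique(subjects[f$test])), 0)
  }
  # each subject's windows land in exactly one test fold
  appearances <- sapply(paste0("s", 1:20), function(s) {
    sum(vapply(folds, function(f) any(subjects[f$test] == s), logical(1)))
  })
  expect_true(all(appearances == 1))
})

test_that("Youden threshold maximizes J with the stated tie-break", {
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  sc <- c(0.9, 0.8, 0.1, 0.2)
  expect_equal(youden_threshold(pos, sc), 0.5)
  # constant scores: J = 0 at every threshold, lowest candidate returned
  pos2 <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(youden_threshold(pos2, rep(0.5, 4)), -Inf)
  expect_equal(youden_oracle_maxJ(pos2, rep(0.5, 4)), 0)
  expect_error(youden_threshold(c(TRUE, TRUE), c(0.1, 0.2)),
               class = "settledown_argument_error")
})

test_that("Youden threshold equals brute-force enumeration on random scores", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(6:40, 1)
    pos <- stats::runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    # discretized scores force ties between candidates
    sc <- round(stats::runif(n), sample(1:2, 1))
    thr <- youden_threshold(pos, sc)
    expect_equal(youden_J_at(pos, sc, thr), youden_oracle_maxJ(pos, sc),
                 tolerance = 1e-12)
    # no lower candidate achieves the same J
    u <- sort(unique(sc))
    cands <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
    lower <- cands[cands < thr]
    if (length(lower)) {
      expect_true(all(vapply(lower, function(t) youden_J_at(pos, sc, t),
                             numeric(1)) < youden_J_at(pos, sc, thr) - 1e-12))
    }
  }
})

test_that("J at the Youden threshold beats the default 0.5 cut", {
  set.seed(12)
  for (i in 1:30) {
    n <- 40
    pos <- stats::runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    sc <- pmin(1, pmax(0, stats::rnorm(n, 0.4 + 0.2 * pos, 0.2)))
    thr <- youden_threshold(pos, sc)
    expect_gte(youden_J_at(pos, sc, thr), youden_J_at(pos, sc, 0.5) - 1e-12)
  }
})

test_that("AUC is rank-based and invariant to monotone transforms", {
  set.seed(13)
  pos <- stats::runif(50) < 0.4
  sc <- stats::rnorm(50)
  a <- auc_score(pos, sc)
  expect_equal(auc_score(pos, exp(sc)), a, tolerance = 1e-12)
  expect_equal(auc_score(pos, 100 + 3 * sc), a, tolerance = 1e-12)
  expect_equal(auc_score(pos, rank(sc)), a, tolerance = 1e-12)
  # agreement with an independent ROC implementation
  skip_if_not_installed("pROC")
  p <- suppressMessages(pROC::auc(pROC::roc(response = pos, predictor = sc,
                                            quiet = TRUE)))
  expect_equal(a, as.numeric(p), tolerance = 1e-12)
})

test_that("cross-validation separates a separable toy problem", {
  ft <- toy_feature_table(seed = 21)
  cv <- run_cv(ft, rf_params(50), k = 5, seed = 3)
  expect_gte(cv$average[["accuracy"]], 0.99)
  expect_gte(cv$average[["auc"]], 0.99)
  # averages equal recomputation from the per-fold table
  expect_equal(cv$average[["accuracy"]], mean(cv$folds$accuracy))
  expect_equal(cv$average[["auc"]], mean(cv$folds$auc))
})

test_that("cross-validation is reproducible and rejects degenerate input", {
  ft <- small_feature_table()
  cv1 <- run_cv(ft, rf_params(30), k = 5, seed = 17)
  cv2 <- run_cv(ft, rf_params(30), k = 5, seed = 17)
  expect_identical(cv1$folds, cv2$folds)
  single <- ft[ft$group == "SS", ]
  expect_error(run_cv(single, rf_params(30), k = 5),
               class = "settledown_single_class_error")
})

test_that("permuted window labels yield chance-level AUC", {
  ft <- small_feature_table()
  aucs <- vapply(1:5, function(s) {
    ftp <- ft
    ftp$group <- with_seed_test(s, sample(ftp$group))
    run_cv(ftp, rf_params(30), k = 5, seed = s)$average[["auc"]]
  }, numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("grid search picks the best cell with a deterministic tie-break", {
  grid <- data.frame(n_trees = 40, max_depth = Inf)
  ft <- toy_feature_table(seed = 22)
  one <- grid_search_params(ft, grid, inner_folds = 3, seed = 5)
  expect_equal(one$n_trees, 40)
  expect_equal(one$max_depth, Inf)
  # separable data: every cell reaches AUC 1, smallest model wins
  grid <- expand.grid(n_trees = c(30, 60), max_depth = c(3, Inf))
  best <- grid_search_params(ft, grid, inner_folds = 3, seed = 5)
  expect_equal(best$n_trees, 30)
  expect_equal(best$max_depth, 3)
  best2 <- grid_search_params(ft, grid, inner_folds = 3, seed = 5)
  expect_equal(attr(best, "grid")$auc, attr(best2, "grid")$auc)
  expect_error(grid_search_params(ft, grid[0, ], seed = 5),
               class = "settledown_argument_error")
})
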