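ts <- function(x) as.POSIXct(x, tz = "UTC")

night_series <- function(n = 600, start = "2021-10-01 18:00:00") {
  activity_series("c1", ts(start), round(stats::rexp(n, 1 / 500)))
}

test_that("diary-mode extraction cuts [settling start, onset)", {
  set.seed(1)
  s <- night_series()
  p <- extract_settling(s, ts("2021-10-01 21:00:00"),
                        ts("2021-10-01 21:45:00"), as.Date("2021-10-01"), "SS")
  expect_period(p)
  expect_equal(p$duration_min, 45)
  expect_length(p$counts, 45)
  expect_equal(p$start, ts("2021-10-01 21:00:00"))
  expect_equal(p$end, ts("2021-10-01 21:45:00"))
  expect_equal(p$counts, s$counts[181:225])
})

test_that("rejections carry typed reason codes", {
  set.seed(2)
  s <- night_series()
  r <- extract_settling(s, ts("2021-10-01 21:00:00"),
                        ts("2021-10-01 20:55:00"), as.Date("2021-10-01"))
  expect_s3_class(r, "settling_rejection")
  expect_equal(r$reason, "onset_before_start")
  r <- extract_settling(s, as.POSIXct(NA, tz = "UTC"),
                        ts("2021-10-01 21:45:00"), as.Date("2021-10-01"))
  expect_equal(r$reason, "no_diary")
  r <- extract_settling(s, ts("2021-10-01 21:00:00"), as.POSIXct(NA, tz = "UTC"),
                        as.Date("2021-10-01"))
  expect_equal(r$reason, "no_onset")
  r <- extract_settling(s, ts("2021-10-01 21:43:00"),
                        ts("2021-10-01 21:45:00"), as.Date("2021-10-01"))
  expect_equal(r$reason, "too_short")
})

test_that("fixed-offset mode ignores the diary and takes 60 min before onset", {
  set.seed(3)
  s <- night_series()
  p <- extract_settling(s, as.POSIXct(NA, tz = "UTC"),
                        ts("2021-10-01 22:00:00"), as.Date("2021-10-01"),
                        mode = "fixed_offset")
  expect_period(p)
  expect_equal(p$start, ts("2021-10-01 21:00:00"))
  expect_equal(p$end, ts("2021-10-01 22:00:00"))
  expect_equal(p$duration_min, 60)
})

test_that("inclusion removes children with fewer than four valid nights", {
  mk <- function(id, n) {
    lapply(seq_len(n), function(j) {
      make_period(rep(1, 10), child_id = id,
                  night_date = as.Date("2021-10-01") + j)
    })
  }
  periods <- c(mk("a", 3), mk("b", 4), mk("c", 6))
  out <- apply_inclusion(periods, min_nights = 4)
  kept <- unique(vapply(out$periods, `[[`, character(1), "child_id"))
  expect_setequal(kept, c("b", "c"))
  expect_equal(out$excluded$child_id, "a")
  expect_equal(out$excluded$n_nights, 3)
  empty <- apply_inclusion(list())
  expect_length(empty$periods, 0)
})

test_that("duration bookkeeping holds across a scored cohort", {
  cohort <- generate_cohort(small_cohort_config(seed = 55))
  periods <- cohort_periods(cohort)
  expect_gt(length(periods), 0)
  for (p in periods) {
    expect_length(p$counts, p$duration_min)
    expect_equal(as.numeric(p$end - p$start, units = "mins"), p$duration_min)
    expect_true(all(p$counts >= 0))
  }
})

test_that("zero diary noise and true onsets recover the exact durations", {
  cohort <- generate_cohort(small_cohort_config(seed = 66, diary_noise_sd = 0,
                                                missing_diary_prob = 0))
  ds <- as_cohort_dataset(cohort)
  tr <- cohort$truth
  match_dur <- vapply(seq_len(nrow(tr)), function(j) {
    p <- extract_settling(ds$series[[tr$child_id[j]]],
                          tr$true_settling_start[j], tr$true_onset[j],
                          tr$night_date[j])
    inherits(p, "settling_period") &&
      p$duration_min == tr$true_duration_min[j]
  }, logical(1))
  expect_gte(mean(match_dur), 0.95)
})

test_that("Hedges' g follows its small-sample-corrected formula", {
  expect_equal(hedges_g(5, 2, 10, 5, 2, 10), 0)
  expect_equal(hedges_g(1, 1, 20, 0, 1, 20), (1 - 3 / 151) * 1,
               tolerance = 1e-12)
  expect_equal(hedges_g(1, 1, 20, 0, 1, 20), 0.980, tolerance = 1e-3)
  # published group moments give ~0.905 under this formula
  g <- hedges_g(52.63, 38.31, 17, 26.19, 14.20, 18)
  expect_equal(g, 0.9047, tolerance = 1e-3)
  # antisymmetry
  set.seed(4)
  for (i in 1:20) {
    m <- stats::rnorm(2, 10, 5)
    s <- stats::runif(2, 0.5, 4)
    n <- sample(5:30, 2, replace = TRUE)
    expect_equal(hedges_g(m[1], s[1], n[1], m[2], s[2], n[2]),
                 -hedges_g(m[2], s[2], n[2], m[1], s[1], n[1]),
                 tolerance = 1e-12)
  }
  expect_error(hedges_g(1, 0, 10, 2, 0, 10),
               class = "settledown_argument_error")
  expect_error(hedges_g(1, 1, 1, 2, 1, 10),
               class = "settledown_argument_error")
})

test_that("duration summaries separate per-subject and per-night framings", {
  periods <- list(
    make_period(rep(1, 40), child_id = "a", group = "SS"),
    make_period(rep(1, 60), child_id = "a", group = "SS",
                night_date = as.Date("2021-10-02")),
    make_period(rep(1, 20), child_id = "b", group = "NSS"),
    make_period(rep(1, 30), child_id = "b", group = "NSS",
                night_date = as.Date("2021-10-02"))
  )
  s <- settling_duration_summary(periods)
  expect_equal(s$per_subject$mean_min[s$per_subject$group == "SS"], 50)
  expect_equal(s$per_night$n[s$per_night$group == "SS"], 2)
  expect_equal(s$per_night$sd_min[s$per_night$group == "NSS"],
               stats::sd(c(20, 30)))
})
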