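test_that("Sadeh discriminant matches hand-evaluated cases", {
  # all-zero activity: every term vanishes
  expect_equal(sadeh_ps(rep(0, 30)), rep(7.601, 30))
  expect_true(all(sadeh_states(rep(0, 30)) == "sleep"))

  # isolated 400-count epoch amid zeros scores wake
  x <- c(rep(0, 20), 400, rep(0, 20))
  ps <- sadeh_ps(x)
  expect_equal(ps[21], sadeh_oracle(x, 21), tolerance = 1e-9)
  expect_equal(ps[21], -8.121, tolerance = 1e-3)
  expect_equal(sadeh_states(x)[21], "wake")

  # constant 75 counts: all 11 window epochs hit the 50-100 band
  y <- rep(75, 40)
  interior <- sadeh_ps(y)[20]
  expect_equal(interior, 7.601 - 0.065 * 75 - 1.08 * 11 - 0.703 * log(76),
               tolerance = 1e-9)
})

test_that("vectorized Sadeh scores equal the scalar oracle everywhere", {
  set.seed(42)
  for (rep in 1:5) {
    x <- round(stats::rexp(200, 1 / stats::runif(1, 5, 2000)))
    ps <- sadeh_ps(x)
    ora <- vapply(seq_along(x), function(i) sadeh_oracle(x, i), numeric(1))
    expect_equal(ps, ora, tolerance = 1e-9)
  }
})

test_that("Sadeh PS decreases as activity statistics increase", {
  # constant quiet series: raising the level raises MW and LG only
  levels <- c(0, 10, 20, 30, 40)
  ps <- vapply(levels, function(c) sadeh_ps(rep(c, 30))[15], numeric(1))
  expect_true(all(diff(ps) < 0))
  # moving one nearby epoch into the 50-100 band adds a NAT hit
  base <- rep(0, 30)
  with_nat <- base
  with_nat[18] <- 75  # inside epoch 15's centered window, outside its SD6 span
  expect_lt(sadeh_ps(with_nat)[15], sadeh_ps(base)[15])
  # inflating the current epoch raises SD6 and LG
  hi <- base
  hi[15] <- 300
  expect_lt(sadeh_ps(hi)[15], sadeh_ps(base)[15])
})

test_that("rest-period detection matches the stated rule on crafted runs", {
  expect_equal(nrow(detect_rest_periods(rep("wake", 500))), 0)

  one <- c(rep("wake", 30), rep("sleep", 600), rep("wake", 30))
  p <- detect_rest_periods(one)
  expect_equal(p$start, 31)
  expect_equal(p$end, 631)
  expect_equal(p$length_min, 600)

  # W20 S5 W3 S200 W10: the 3-epoch wake interruption does not end the
  # period, so it spans from the first 5-sleep run to the final wake run
  states <- rep(c("wake", "sleep", "wake", "sleep", "wake"),
                c(20, 5, 3, 200, 10))
  p <- detect_rest_periods(states, onset_run = 5, offset_run = 10,
                           min_rest_minutes = 160)
  ora <- rest_periods_oracle(states, 5, 10, 160)
  expect_equal(p[, c("start", "end")], ora)
  expect_equal(p$start, 21)
  expect_equal(p$end, 229)
})

test_that("rest-period detection equals the exhaustive oracle on random labels", {
  set.seed(7)
  for (rep in 1:100) {
    n <- sample(50:300, 1)
    states <- ifelse(stats::runif(n) < stats::runif(1, 0.2, 0.8),
                     "sleep", "wake")
    onset <- sample(2:6, 1)
    offset <- sample(3:12, 1)
    min_rest <- sample(c(5, 20, 60), 1)
    got <- detect_rest_periods(states, onset, offset, min_rest)
    ora <- rest_periods_oracle(states, onset, offset, min_rest)
    expect_equal(got[, c("start", "end")], ora)
  }
})

test_that("the 30-minute diary rule adjusts starts only for close reports", {
  ts <- function(x) as.POSIXct(paste("2021-10-01", x), tz = "UTC")
  period <- data.frame(start = ts("22:10:00"), end = ts("07:00:00") + 86400)
  close <- reconcile_with_diary(period, ts("22:00:00"))
  expect_equal(close$start, ts("22:00:00"))
  expect_equal(close$source, "diary_adjusted")
  far <- reconcile_with_diary(period, ts("21:25:00"))  # 45 min apart
  expect_equal(far$start, ts("22:10:00"))
  expect_equal(far$source, "algorithm")
  # a difference of exactly 30 minutes counts as "30+": algorithm kept
  boundary <- reconcile_with_diary(period, ts("21:40:00"))
  expect_equal(boundary$start, ts("22:10:00"))
  expect_equal(boundary$source, "algorithm")
  missing <- reconcile_with_diary(period, as.POSIXct(NA, tz = "UTC"))
  expect_equal(missing$source, "algorithm")
})

test_that("sleep onset is the first sustained sleep run", {
  expect_equal(sleep_onset_index(rep("sleep", 10)), 1)
  st <- c("wake", "wake", "sleep", "wake", "sleep", "sleep", "sleep", "wake")
  expect_equal(sleep_onset_index(st, 3), 5)
  expect_true(is.na(sleep_onset_index(c("wake", "sleep", "sleep", "wake"), 3)))
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(10:80, 1)
    st <- ifelse(stats::runif(n) < 0.5, "sleep", "wake")
    k <- sample(2:4, 1)
    expect_equal(sleep_onset_index(st, k), first_sleep_run_oracle(st, k))
  }
})

test_that("algorithmic onset recovers the generator's true onset", {
  cohort <- generate_cohort(small_cohort_config(seed = 77))
  nights <- score_nights(as_cohort_dataset(cohort))
  m <- merge(nights, cohort$truth, by = c("child_id", "night_date"))
  expect_gt(mean(m$valid), 0.9)
  err <- as.numeric(m$onset - m$true_onset, units = "mins")
  expect_lte(stats::median(abs(err), na.rm = TRUE), 5)
})
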