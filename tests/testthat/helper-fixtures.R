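# Shared fixtures, all generated in code at test time.

# A small but structurally complete cohort used by scoring/extraction tests.
small_cohort_config <- function(seed = 404, ...) {
  cohort_config(n_ss = 5, n_nss = 5, nights_range = c(5, 7), seed = seed, ...)
}

# Cohort -> included settling periods via the full scoring path.
cohort_periods <- function(cohort, mode = "diary") {
  ds <- as_cohort_dataset(cohort)
  nights <- score_nights(ds)
  ext <- extract_all_settling(ds, nights, mode = mode)
  apply_inclusion(ext$periods)$periods
}

# Feature table cached across test files (built once per test run).
.fixture_env <- new.env(parent = emptyenv())
small_feature_table <- function() {
  if (is.null(.fixture_env$ft)) {
    cohort <- generate_cohort(small_cohort_config())
    .fixture_env$ft <- build_feature_table(cohort_periods(cohort), 11, 1)
  }
  .fixture_env$ft
}

# Hand-built settling period for unit tests.
make_period <- function(counts, child_id = "c1", group = "SS",
                        night_date = as.Date("2021-10-01"),
                        start = as.POSIXct("2021-10-01 21:00:00", tz = "UTC")) {
  structure(
    list(child_id = child_id, night_date = night_date, group = group,
         start = start, end = start + 60 * length(counts), counts = counts,
         duration_min = length(counts)),
    class = "settling_period"
  )
}

# A separable toy feature table: SS and NSS windows drawn from well-separated
# Gaussians in every feature.
toy_feature_table <- function(n_per_group = 100, n_subjects = 10, shift = 10,
                              seed = 1) {
  set.seed(seed)
  fn <- feature_names()
  mk <- function(group, mu, prefix) {
    m <- matrix(stats::rnorm(n_per_group * length(fn), mu), n_per_group)
    colnames(m) <- fn
    cbind(
      data.frame(
        child_id = rep(sprintf("%s%02d", prefix, seq_len(n_subjects)),
                       length.out = n_per_group),
        night_date = as.Date("2021-10-01"), group = group,
        window_start = as.POSIXct("2021-10-01 21:00:00", tz = "UTC") +
          60 * seq_len(n_per_group),
        stringsAsFactors = FALSE),
      as.data.frame(m)
    )
  }
  rbind(mk("SS", shift, "S"), mk("NSS", 0, "N"))
}

expect_period <- function(x) expect_s3_class(x, "settling_period")

# Evaluate code under a temporary seed without disturbing the test RNG.
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
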