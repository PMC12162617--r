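# Rolling-window feature extraction from settling periods.
#
# Each settling period is sliced into fixed-length windows advanced by a
# stride, and every window is summarized by seven features: mean magnitude,
# maximum magnitude, kurtosis, skewness, Shannon entropy, standard deviation
# and interquartile range. Windows multiply the training instances from each
# night while keeping patterns local in time.

#' Rolling window start offsets
#'
#' Windows are the sub-sequences starting at epochs `0, S, 2S, ...` of length
#' `W` that fit entirely inside the period, giving
#' `floor((L - W) / S) + 1` windows for `L >= W` and none otherwise.
#'
#' @param counts numeric vector of period epoch counts.
#' @param window_min window length `W` in minutes (>= 3).
#' @param stride_min stride `S` in minutes (>= 1).
#' @return list of numeric windows (possibly empty).
#' @export
roll_windows <- function(counts, window_min, stride_min = 1) {
  stopifnot(window_min >= 3, stride_min >= 1)
  L <- length(counts)
  if (L < window_min) return(list())
  starts <- seq(1L, L - window_min + 1L, by = stride_min)
  lapply(starts, function(s) counts[s:(s + window_min - 1L)])
}

#' Shannon entropy of a window, in bits
#'
#' Entropy of the empirical distribution of the distinct count values in the
#' window: `H = -sum(p_i * log2(p_i))` with `p_i` the relative multiplicity
#' of each distinct value. `H` ranges from 0 (all epochs equal) to
#' `log2(length(counts))` (all epochs distinct), so it measures
#' moment-to-moment variability of activity.
#'
#' @param counts non-empty numeric vector.
#' @return entropy in bits.
#' @examples
#' shannon_entropy_bits(c(0, 0, 0, 50, 100, 100))  # ~1.459
#' @export
shannon_entropy_bits <- function(counts) {
  if (length(counts) == 0L) {
    stop_settledown("counts must be non-empty", "settledown_argument_error")
  }
  p <- tabulate(match(counts, unique(counts))) / length(counts)
  -sum(p * log2(p))
}

#' Seven summary features of one window
#'
#' Mean, maximum, sample (n-1) standard deviation, interquartile range
#' (linear-interpolation quantiles), moment skewness `m3 / m2^(3/2)`, excess
#' kurtosis `m4 / m2^2 - 3` (central moments with denominator `n`), and
#' Shannon entropy in bits. Degenerate windows with zero variance have
#' skewness and kurtosis defined as 0.
#'
#' @param counts numeric vector of length >= 3.
#' @return named numeric vector with elements `mean_mag`, `max_mag`,
#'   `kurtosis`, `skewness`, `entropy_bits`, `sd`, `iqr`.
#' @export
compute_features <- function(counts) {
  n <- length(counts)
  if (n < 3L) {
    stop_settledown("a window needs at least 3 epochs",
                    "settledown_argument_error")
  }
  m <- mean(counts)
  dev <- counts - m
  m2 <- mean(dev^2)
  if (m2 > 0) {
    skew <- mean(dev^3) / m2^1.5
    kurt <- mean(dev^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  c(mean_mag = m, max_mag = max(counts), kurtosis = kurt, skewness = skew,
    entropy_bits = shannon_entropy_bits(counts), sd = stats::sd(counts),
    iqr = unname(stats::quantile(counts, 0.75) - stats::quantile(counts, 0.25)))
}

#' Build the window feature table for a cohort
#'
#' One row per rolling window, carrying subject, night and group metadata, in
#' deterministic (child, night, window start) order. Periods shorter than the
#' window yield no rows and are reported in the `skipped` attribute rather
#' than truncated, so all windows share one length and entropy bounds and
#' moments stay comparable.
#'
#' @param periods list of `settling_period` objects.
#' @param window_min,stride_min window specification, see [roll_windows()].
#' @return data frame with columns `child_id`, `night_date`, `group`,
#'   `window_start` and the seven features; attribute `skipped` lists periods
#'   shorter than the window.
#' @export
build_feature_table <- function(periods, window_min = 11, stride_min = 1) {
  feat_names <- c("mean_mag", "max_mag", "kurtosis", "skewness",
                  "entropy_bits", "sd", "iqr")
  rows <- vector("list", length(periods))
  skipped <- list()
  for (i in seq_along(periods)) {
    p <- periods[[i]]
    wins <- roll_windows(p$counts, window_min, stride_min)
    if (length(wins) == 0L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        child_id = p$child_id, night_date = p$night_date,
        duration_min = p$duration_min, stringsAsFactors = FALSE)
      next
    }
    feats <- t(vapply(wins, compute_features, numeric(7)))
    starts <- p$start + 60 * stride_min * (seq_along(wins) - 1L)
    rows[[i]] <- cbind(
      data.frame(child_id = p$child_id, night_date = p$night_date,
                 group = p$group, window_start = starts,
                 stringsAsFactors = FALSE),
      as.data.frame(feats)
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(child_id = character(0),
                     night_date = as.Date(character(0)),
                     group = character(0),
                     window_start = as.POSIXct(character(0), tz = "UTC")),
          stats::setNames(as.data.frame(matrix(numeric(0), 0, 7)), feat_names))
  out <- out[order(out$child_id, out$night_date, out$window_start), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  attr(out, "window_min") <- window_min
  attr(out, "stride_min") <- stride_min
  out
}

#' Names of the window feature columns
#' @return character vector of the seven feature names.
#' @export
feature_names <- function() {
  c("mean_mag", "max_mag", "kurtosis", "skewness", "entropy_bits", "sd", "iqr")
}
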