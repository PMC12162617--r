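# Per-epoch sleep-wake scoring and nightly rest-period isolation.
#
# The scorer is the Sadeh discriminant, a pediatric actigraphy rule:
#   PS = 7.601 - 0.065*MW - 1.08*NAT - 0.056*SD6 - 0.703*LG
# where, for epoch i,
#   MW  = mean counts over the 11-epoch window centered on i,
#   NAT = number of epochs in that window with counts in [50, 100),
#   SD6 = sample (n-1) standard deviation of the current and 5 preceding
#         epochs,
#   LG  = natural log of (current counts + 1),
# and the epoch is scored sleep iff PS >= 0. The series is zero-padded by 5
# epochs on each side so the discriminant is defined at the boundaries.
#
# Nightly rest periods are then delimited with consecutive-epoch rules in the
# Tudor-Locke style (default onset run 5 sleep epochs, offset run 10 wake
# epochs, minimum length 160 min), reconciled against the caregiver diary
# with the 30-minute rule, and sleep onset is the first sustained sleep run
# inside the period.

rolling_sum <- function(x, k) {
  cs <- cumsum(c(0, x))
  cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]
}

#' Sadeh sleep-wake discriminant for every epoch
#'
#' @param counts numeric vector of per-minute vector-magnitude counts.
#' @return numeric vector of PS values, one per epoch (sleep iff `PS >= 0`).
#' @examples
#' sadeh_ps(rep(0, 20))[1]  # quiet epochs score 7.601
#' @export
sadeh_ps <- function(counts) {
  if (inherits(counts, "activity_series")) counts <- counts$counts
  n <- length(counts)
  if (n == 0L) return(numeric(0))
  x <- c(rep(0, 5), as.numeric(counts), rep(0, 5))
  # centered 11-epoch window statistics; element i of the rolling vectors
  # corresponds to original epoch i
  mw <- rolling_sum(x, 11L) / 11
  nat <- rolling_sum(as.numeric(x >= 50 & x < 100), 11L)
  # SD6: current + 5 preceding epochs; for original epoch i this is padded
  # positions (i .. i+5), i.e. rolling windows of width 6 starting at i
  s1 <- rolling_sum(x, 6L)
  s2 <- rolling_sum(x^2, 6L)
  v6 <- pmax(0, (s2 - s1^2 / 6) / 5)
  sd6 <- sqrt(v6)[seq_len(n)]
  lg <- log(as.numeric(counts) + 1)
  7.601 - 0.065 * mw[seq_len(n)] - 1.08 * nat[seq_len(n)] - 0.056 * sd6 -
    0.703 * lg
}

#' Sleep/wake state per epoch
#'
#' @param counts numeric vector of per-minute counts (or an
#'   [activity_series()]).
#' @return character vector, `"sleep"` where the Sadeh PS is non-negative,
#'   else `"wake"`.
#' @export
sadeh_states <- function(counts) {
  ifelse(sadeh_ps(counts) >= 0, "sleep", "wake")
}

#' Detect nightly rest periods from scored epochs
#'
#' A rest period begins at the first epoch of a run of at least `onset_run`
#' consecutive sleep-scored epochs and ends at the first epoch of the next
#' run of at least `offset_run` consecutive wake-scored epochs (or at the end
#' of the series). Periods shorter than `min_rest_minutes` are discarded.
#'
#' @param states character vector of `"sleep"`/`"wake"` labels (or an
#'   [activity_series()], which is scored with [sadeh_states()] first).
#' @param onset_run,offset_run,min_rest_minutes consecutive-epoch rules.
#' @return data frame with one row per period: `start`, `end` (1-based epoch
#'   indices, half-open `[start, end)`) and `length_min`.
#' @export
detect_rest_periods <- function(states, onset_run = 5, offset_run = 10,
                                min_rest_minutes = 160) {
  if (inherits(states, "activity_series")) states <- sadeh_states(states)
  n <- length(states)
  out <- data.frame(start = integer(0), end = integer(0),
                    length_min = integer(0))
  if (n == 0L) return(out)
  r <- rle(states == "sleep")
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  i <- 1L
  while (i <= length(r$lengths)) {
    if (r$values[i] && r$lengths[i] >= onset_run) {
      start <- run_start[i]
      j <- i + 1L
      end <- n + 1L
      while (j <= length(r$lengths)) {
        if (!r$values[j] && r$lengths[j] >= offset_run) {
          end <- run_start[j]
          break
        }
        j <- j + 1L
      }
      if (end - start >= min_rest_minutes) {
        out <- rbind(out, data.frame(start = start, end = end,
                                     length_min = end - start))
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Reconcile a rest period with the caregiver diary
#'
#' Implements the 30-minute rule: when the caregiver-reported sleep onset
#' differs from the algorithm-identified period start by strictly less than
#' `threshold_min` minutes, the reported time is used; when they differ by 30
#' or more minutes ("30+"), the algorithmic time is kept. The period end is
#' never adjusted here because the diary dialect carries no morning report.
#'
#' @param period one-row data frame with `start`/`end` `POSIXct` columns (as
#'   produced by [score_nights()] internals).
#' @param reported_sleep_onset `POSIXct` caregiver-reported onset (or `NA`).
#' @param threshold_min reconciliation threshold in minutes.
#' @return the period with possibly adjusted `start` and a `source` column,
#'   `"algorithm"` or `"diary_adjusted"`.
#' @export
reconcile_with_diary <- function(period, reported_sleep_onset,
                                 threshold_min = 30) {
  period$source <- "algorithm"
  if (is.null(reported_sleep_onset) || length(reported_sleep_onset) == 0L ||
      is.na(reported_sleep_onset)) {
    return(period)
  }
  diff_min <- abs(as.numeric(reported_sleep_onset - period$start,
                             units = "mins"))
  if (diff_min < threshold_min && reported_sleep_onset < period$end) {
    period$start <- reported_sleep_onset
    period$source <- "diary_adjusted"
  }
  period
}

#' Sleep onset within a rest period
#'
#' Onset is the first epoch inside the period that begins a run of at least
#' `onset_consecutive` sleep-scored epochs; a night with no such run is
#' flagged invalid (and excluded downstream).
#'
#' @param states character sleep/wake labels for the epochs of the period.
#' @param onset_consecutive required run length (default 3).
#' @return 1-based index of the onset epoch within the period, or `NA_integer_`
#'   if no qualifying run exists.
#' @export
sleep_onset_index <- function(states, onset_consecutive = 3) {
  if (length(states) == 0L) return(NA_integer_)
  r <- rle(states == "sleep")
  run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  hit <- which(r$values & r$lengths >= onset_consecutive)
  if (length(hit) == 0L) NA_integer_ else run_start[hit[1L]]
}

#' Score every night of a cohort
#'
#' For each child and each noon-to-noon night in its series: scores epochs
#' with the Sadeh rule, detects rest periods, keeps the longest (earliest on
#' ties), reconciles its start with the diary-reported sleep onset via the
#' 30-minute rule, and locates algorithmic sleep onset within the period.
#'
#' @param dataset a `cohort_dataset` from [assemble_dataset()].
#' @param onset_run,offset_run,min_rest_minutes rest-period rules, see
#'   [detect_rest_periods()].
#' @param onset_consecutive sleep-onset run length, see [sleep_onset_index()].
#' @param reconcile_threshold_min diary reconciliation threshold (minutes);
#'   set to 0 to disable diary adjustment.
#' @return data frame with one row per night: `child_id`, `night_date`,
#'   `rest_start`, `rest_end`, `rest_source`, `onset` (`POSIXct`, `NA` when
#'   invalid), `onset_method` and `valid`.
#' @export
score_nights <- function(dataset, onset_run = 5, offset_run = 10,
                         min_rest_minutes = 160, onset_consecutive = 3,
                         reconcile_threshold_min = 30) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  rows <- list()
  for (s in dataset$series) {
    states <- sadeh_states(s)
    times <- epoch_times(s)
    first_noon <- as.POSIXct(paste(format(times[1L], "%Y-%m-%d", tz = "UTC"),
                                   "12:00:00"), tz = "UTC")
    if (first_noon > times[1L]) first_noon <- first_noon - 86400
    n_nights <- ceiling(as.numeric(times[length(times)] - first_noon,
                                   units = "days"))
    for (j in seq_len(n_nights)) {
      w0 <- first_noon + (j - 1) * 86400
      idx <- which(times >= w0 & times < w0 + 86400)
      if (length(idx) < min_rest_minutes) next
      night_date <- as.Date(format(w0, "%Y-%m-%d", tz = "UTC"))
      periods <- detect_rest_periods(states[idx], onset_run, offset_run,
                                     min_rest_minutes)
      row <- data.frame(child_id = s$child_id, night_date = night_date,
                        rest_start = as.POSIXct(NA, tz = "UTC"),
                        rest_end = as.POSIXct(NA, tz = "UTC"),
                        rest_source = NA_character_,
                        onset = as.POSIXct(NA, tz = "UTC"),
                        onset_method = NA_character_, valid = FALSE,
                        stringsAsFactors = FALSE)
      if (nrow(periods) > 0L) {
        best <- periods[order(-periods$length_min, periods$start), ][1L, ]
        period <- data.frame(start = times[idx[best$start]],
                             end = times[idx[1L]] + 60 * (best$end - 1L))
        diary <- dataset$diary[dataset$diary$child_id == s$child_id &
                                 dataset$diary$night_date == night_date, ]
        rep_onset <- if (nrow(diary) > 0L) diary$reported_sleep_onset[1L] else
          as.POSIXct(NA, tz = "UTC")
        if (reconcile_threshold_min > 0) {
          period <- reconcile_with_diary(period, rep_onset,
                                         reconcile_threshold_min)
        } else period$source <- "algorithm"
        in_period <- which(times >= period$start & times < period$end)
        k <- sleep_onset_index(states[in_period], onset_consecutive)
        row$rest_start <- period$start
        row$rest_end <- period$end
        row$rest_source <- period$source
        if (!is.na(k)) {
          row$onset <- times[in_period[k]]
          row$onset_method <- "sadeh"
          row$valid <- TRUE
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(child_id = character(0), night_date = as.Date(character(0)),
                      rest_start = as.POSIXct(character(0), tz = "UTC"),
                      rest_end = as.POSIXct(character(0), tz = "UTC"),
                      rest_source = character(0),
                      onset = as.POSIXct(character(0), tz = "UTC"),
                      onset_method = character(0), valid = logical(0)))
  }
  do.call(rbind, rows)
}

#' Per-epoch scoring table for export
#'
#' @param series an [activity_series()].
#' @return data frame with `child_id`, `epoch_time`, `ps` and `state` for
#'   every epoch, the exportable form of the per-night scoring output.
#' @export
sadeh_scores_df <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  ps <- sadeh_ps(series$counts)
  data.frame(child_id = series$child_id, epoch_time = epoch_times(series),
             ps = ps, state = ifelse(ps >= 0, "sleep", "wake"),
             stringsAsFactors = FALSE)
}
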