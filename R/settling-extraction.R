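# Cutting the per-night settling-down window and summarizing its duration.
#
# The settling-down period is the slice of the activity series between the
# caregiver-reported settling start (diary mode) and the algorithmic sleep
# onset; a diary-free fallback takes the fixed 60 minutes before onset
# instead. Children contribute only if they retain at least `min_nights`
# valid nights.

#' Extract one night's settling-down period
#'
#' @param series the child's [activity_series()].
#' @param settling_start `POSIXct` caregiver-reported settling start (may be
#'   `NA` in `fixed_offset` mode).
#' @param onset `POSIXct` algorithmic sleep onset for the night (`NA` when
#'   the night is invalid).
#' @param night_date civil date of the night.
#' @param group group label carried onto the period.
#' @param mode `"diary"` uses the window `[settling_start, onset)`;
#'   `"fixed_offset"` uses `[onset - fixed_offset_min, onset)` regardless of
#'   the diary.
#' @param fixed_offset_min window length in minutes for `fixed_offset` mode.
#' @param min_duration minimum admissible duration in minutes (shorter nights
#'   are rejected so variance-based features remain defined).
#' @return A list of class `settling_period` with fields `child_id`,
#'   `night_date`, `group`, `start`, `end`, `counts` and `duration_min`, or a
#'   list of class `settling_rejection` with a `reason` code among
#'   `"no_onset"`, `"no_diary"`, `"onset_before_start"`, `"too_short"`,
#'   `"outside_series"`.
#' @export
extract_settling <- function(series, settling_start, onset, night_date,
                             group = NA_character_,
                             mode = c("diary", "fixed_offset"),
                             fixed_offset_min = 60, min_duration = 3) {
  mode <- match.arg(mode)
  reject <- function(reason) {
    structure(list(child_id = series$child_id, night_date = night_date,
                   reason = reason), class = "settling_rejection")
  }
  if (is.null(onset) || length(onset) == 0L || is.na(onset)) {
    return(reject("no_onset"))
  }
  if (mode == "diary") {
    if (is.null(settling_start) || length(settling_start) == 0L ||
        is.na(settling_start)) {
      return(reject("no_diary"))
    }
    start <- settling_start
  } else {
    start <- onset - 60 * fixed_offset_min
  }
  if (onset <= start) return(reject("onset_before_start"))
  times <- epoch_times(series)
  idx <- which(times >= start & times < onset)
  if (length(idx) == 0L ||
      start < times[1L] || onset > times[length(times)] + 60) {
    return(reject("outside_series"))
  }
  if (length(idx) < min_duration) return(reject("too_short"))
  structure(
    list(child_id = series$child_id, night_date = night_date, group = group,
         start = times[idx[1L]], end = times[idx[length(idx)]] + 60,
         counts = series$counts[idx], duration_min = length(idx)),
    class = "settling_period"
  )
}

#' @export
print.settling_period <- function(x, ...) {
  cat(sprintf("<settling_period> %s %s (%s): %d min from %s\n", x$child_id,
              as.character(x$night_date), x$group, x$duration_min,
              format_ts(x$start)))
  invisible(x)
}

#' Extract settling periods for a whole cohort
#'
#' Joins the per-night scoring output with the diary and cuts every night's
#' settling window.
#'
#' @param dataset a `cohort_dataset`.
#' @param nights the [score_nights()] output.
#' @inheritParams extract_settling
#' @return list with `periods` (list of `settling_period`) and `rejections`
#'   (data frame of reason codes per rejected night).
#' @export
extract_all_settling <- function(dataset, nights,
                                 mode = c("diary", "fixed_offset"),
                                 fixed_offset_min = 60, min_duration = 3) {
  mode <- match.arg(mode)
  periods <- list()
  rej <- list()
  group_of <- stats::setNames(dataset$labels$group, dataset$labels$child_id)
  for (i in seq_len(nrow(nights))) {
    row <- nights[i, ]
    d <- dataset$diary[dataset$diary$child_id == row$child_id &
                         dataset$diary$night_date == row$night_date, ]
    start <- if (nrow(d) > 0L) d$settling_start[1L] else
      as.POSIXct(NA, tz = "UTC")
    p <- extract_settling(dataset$series[[row$child_id]], start, row$onset,
                          row$night_date, group_of[[row$child_id]],
                          mode = mode, fixed_offset_min = fixed_offset_min,
                          min_duration = min_duration)
    if (inherits(p, "settling_period")) {
      periods[[length(periods) + 1L]] <- p
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        child_id = p$child_id, night_date = p$night_date, reason = p$reason,
        stringsAsFactors = FALSE)
    }
  }
  list(periods = periods,
       rejections = if (length(rej)) do.call(rbind, rej) else
         data.frame(child_id = character(0),
                    night_date = as.Date(character(0)),
                    reason = character(0)))
}

#' Enforce the minimum-nights inclusion rule
#'
#' Children with fewer than `min_nights` valid settling periods are removed
#' entirely (at least four evenings are required for a child to contribute).
#'
#' @param periods list of `settling_period` objects.
#' @param min_nights minimum number of valid nights per child.
#' @return list with `periods` (the retained periods) and `excluded` (data
#'   frame of excluded children and their night counts).
#' @export
apply_inclusion <- function(periods, min_nights = 4) {
  if (length(periods) == 0L) {
    return(list(periods = list(),
                excluded = data.frame(child_id = character(0),
                                      n_nights = integer(0))))
  }
  ids <- vapply(periods, `[[`, character(1), "child_id")
  tab <- table(ids)
  drop <- names(tab)[tab < min_nights]
  list(periods = periods[!ids %in% drop],
       excluded = data.frame(child_id = drop,
                             n_nights = as.integer(tab[drop]),
                             row.names = NULL))
}

#' Metadata table of settling periods
#'
#' @param periods list of `settling_period` objects.
#' @return data frame with one row per period (no counts).
#' @export
periods_df <- function(periods) {
  if (length(periods) == 0L) {
    return(data.frame(child_id = character(0),
                      night_date = as.Date(character(0)),
                      group = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      duration_min = integer(0)))
  }
  do.call(rbind, lapply(periods, function(p) {
    data.frame(child_id = p$child_id, night_date = p$night_date,
               group = p$group, start = p$start, end = p$end,
               duration_min = p$duration_min, stringsAsFactors = FALSE)
  }))
}

#' Group summaries of settling-down duration
#'
#' Two framings are produced: `per_subject` first averages each child's
#' nightly durations and then summarizes subjects within group (the framing
#' used for subject-level group comparisons), and `per_night` pools all
#' nights within group.
#'
#' @param periods list of `settling_period` objects.
#' @return list of two data frames (`per_subject`, `per_night`) with columns
#'   `group`, `mean_min`, `sd_min`, `n`.
#' @export
settling_duration_summary <- function(periods) {
  df <- periods_df(periods)
  summarize <- function(values, groups) {
    out <- lapply(split(values, groups), function(v) {
      data.frame(mean_min = mean(v), sd_min = stats::sd(v), n = length(v))
    })
    cbind(data.frame(group = names(out)), do.call(rbind, out),
          row.names = NULL)
  }
  subj_mean <- tapply(df$duration_min, df$child_id, mean)
  subj_group <- tapply(df$group, df$child_id, `[`, 1L)
  list(per_subject = summarize(as.numeric(subj_mean), as.character(subj_group)),
       per_night = summarize(df$duration_min, df$group))
}

#' Hedges' g standardized mean difference
#'
#' `g = J * (m1 - m2) / s_pooled` with the pooled SD
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))` and the
#' small-sample correction `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)`.
#'
#' @param m1,s1,n1 mean, SD and size of the first sample.
#' @param m2,s2,n2 mean, SD and size of the second sample.
#' @return Hedges' g (positive when the first mean is larger).
#' @examples
#' hedges_g(1, 1, 20, 0, 1, 20)  # ~0.980
#' @export
hedges_g <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) {
    stop_settledown("both samples need n >= 2", "settledown_argument_error")
  }
  if (s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0)) {
    stop_settledown("pooled variance is zero; effect size undefined",
                    "settledown_argument_error")
  }
  df <- n1 + n2 - 2
  s_pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df)
  j <- 1 - 3 / (4 * df - 1)
  j * (m1 - m2) / s_pooled
}
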