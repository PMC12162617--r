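# Reading, writing and assembling the epoch-activity, diary and label file
# dialects. Timestamps are ISO-8601 local clock time; internally they are
# represented as POSIXct in UTC so no timezone arithmetic is ever applied.
# Epoch intervals are half-open [t, t + 60 s), and all downstream slicing
# follows the same convention.

#' Construct an epoch-level activity series
#'
#' An `activity_series` holds one child's contiguous sequence of 60-second
#' epochs with vector-magnitude activity counts, the native unit of
#' ActiLife-style actigraphy exports.
#'
#' @param child_id character scalar identifier.
#' @param start_time `POSIXct` timestamp of the first epoch.
#' @param counts numeric vector of non-negative vector-magnitude counts, one
#'   per epoch. Epoch `i` covers `[start_time + 60*(i-1), start_time + 60*i)`.
#' @param epoch_seconds epoch duration; fixed at 60.
#' @param axis_counts optional list of three numeric vectors (`axis1..3`)
#'   parallel to `counts`.
#' @return An object of class `activity_series`.
#' @examples
#' s <- activity_series("c1", as.POSIXct("2021-10-01 20:00:00", tz = "UTC"),
#'                      counts = c(0, 120, 35))
#' epoch_times(s)
#' @export
activity_series <- function(child_id, start_time, counts, epoch_seconds = 60,
                            axis_counts = NULL) {
  if (epoch_seconds != 60) {
    stop_settledown("epoch_seconds must be 60", "settledown_format_error")
  }
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) {
    bad <- which(is.na(counts) | counts < 0)[1L]
    stop_settledown(sprintf("negative or missing count at epoch %d", bad),
                    "settledown_format_error")
  }
  if (!inherits(start_time, "POSIXct") || length(start_time) != 1L) {
    stop_settledown("start_time must be a single POSIXct",
                    "settledown_format_error")
  }
  if (!is.null(axis_counts)) {
    stopifnot(is.list(axis_counts), length(axis_counts) == 3L,
              all(lengths(axis_counts) == length(counts)))
  }
  structure(
    list(child_id = as.character(child_id), start_time = start_time,
         epoch_seconds = 60, counts = counts, axis_counts = axis_counts),
    class = "activity_series"
  )
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> child %s: %d epochs of %ds from %s\n",
              x$child_id, length(x$counts), x$epoch_seconds,
              format_ts(x$start_time)))
  invisible(x)
}

#' @export
length.activity_series <- function(x) length(x$counts)

#' Epoch start times of an activity series
#'
#' @param series an [activity_series()].
#' @return `POSIXct` vector of epoch start times.
#' @export
epoch_times <- function(series) {
  series$start_time + series$epoch_seconds * (seq_along(series$counts) - 1)
}

#' Read an epoch-activity CSV
#'
#' Expects the dialect `timestamp,axis1,axis2,axis3,vector_magnitude` with the
#' axis columns optional, rows sorted by time, one row per 60-s epoch.
#' Rejects duplicated or non-contiguous timestamps and negative counts, naming
#' the offending row.
#'
#' @param path file path.
#' @param child_id identifier to attach; defaults to the file name without
#'   extension.
#' @return An [activity_series()].
#' @export
read_epoch_csv <- function(path, child_id = NULL) {
  if (is.null(child_id)) {
    child_id <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("timestamp", "vector_magnitude")
  if (!all(need %in% names(df))) {
    stop_settledown(
      sprintf("epoch CSV must have columns %s", paste(need, collapse = ", ")),
      "settledown_format_error"
    )
  }
  ts <- parse_ts(df$timestamp)
  if (anyNA(ts)) {
    stop_settledown(sprintf("unparseable timestamp at row %d",
                            which(is.na(ts))[1L]), "settledown_format_error")
  }
  if (nrow(df) > 1L) {
    d <- as.numeric(diff(ts), units = "secs")
    if (any(d == 0)) {
      stop_settledown(sprintf("duplicate timestamp at row %d",
                              which(d == 0)[1L] + 1L),
                      "settledown_format_error")
    }
    if (any(d != 60)) {
      stop_settledown(sprintf("non-contiguous epochs at row %d (gap of %gs)",
                              which(d != 60)[1L] + 1L, d[d != 60][1L]),
                      "settledown_format_error")
    }
  }
  if (any(df$vector_magnitude < 0)) {
    stop_settledown(sprintf("negative count at row %d",
                            which(df$vector_magnitude < 0)[1L]),
                    "settledown_format_error")
  }
  axis <- NULL
  if (all(c("axis1", "axis2", "axis3") %in% names(df))) {
    axis <- list(axis1 = df$axis1, axis2 = df$axis2, axis3 = df$axis3)
  }
  activity_series(child_id, ts[1L], df$vector_magnitude, axis_counts = axis)
}

#' Write an epoch-activity CSV
#'
#' Inverse of [read_epoch_csv()]; the round trip preserves timestamps exactly
#' and counts to full double precision.
#'
#' @param series an [activity_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  df <- data.frame(timestamp = format_ts(epoch_times(series)),
                   stringsAsFactors = FALSE)
  if (!is.null(series$axis_counts)) {
    df$axis1 <- series$axis_counts$axis1
    df$axis2 <- series$axis_counts$axis2
    df$axis3 <- series$axis_counts$axis3
  }
  df$vector_magnitude <- series$counts
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Resolve an evening clock time ("HH:MM") against the diary's night date.
# Times between midnight and 06:00 belong to the morning after the night's
# civil date, so they are pushed one day forward; the night keeps the date on
# which settling started.
resolve_evening_time <- function(night_date, hhmm) {
  out <- as.POSIXct(paste(as.character(night_date), hhmm), tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  hr <- as.integer(format(out, "%H"))
  out[!is.na(out) & hr < 6L] <- out[!is.na(out) & hr < 6L] + 86400
  out
}

#' Read a sleep-diary CSV
#'
#' Dialect: `child_id,night_date,settling_start,reported_sleep_onset` with
#' times given as `HH:MM` clock times. Clock times before 06:00 are attributed
#' to the morning after `night_date` (the night keeps the evening's civil
#' date). `reported_sleep_onset` may be empty.
#'
#' @param path file path.
#' @return data frame with columns `child_id`, `night_date` (`Date`),
#'   `settling_start` and `reported_sleep_onset` (`POSIXct`, the latter `NA`
#'   when unreported).
#' @export
read_diary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character", strip.white = TRUE)
  need <- c("child_id", "night_date", "settling_start")
  if (!all(need %in% names(df))) {
    stop_settledown(
      sprintf("diary CSV must have columns %s", paste(need, collapse = ", ")),
      "settledown_format_error"
    )
  }
  night_date <- as.Date(df$night_date)
  if (anyNA(night_date)) {
    stop_settledown(sprintf("unparseable night_date at row %d",
                            which(is.na(night_date))[1L]),
                    "settledown_format_error")
  }
  start <- resolve_evening_time(night_date, df$settling_start)
  if (anyNA(start)) {
    stop_settledown(sprintf("unparseable settling_start at row %d",
                            which(is.na(start))[1L]), "settledown_format_error")
  }
  onset <- rep(as.POSIXct(NA, tz = "UTC"), nrow(df))
  if ("reported_sleep_onset" %in% names(df)) {
    has <- !is.na(df$reported_sleep_onset) & nzchar(df$reported_sleep_onset)
    onset[has] <- resolve_evening_time(night_date[has],
                                       df$reported_sleep_onset[has])
    if (anyNA(onset[has])) {
      stop_settledown("unparseable reported_sleep_onset",
                      "settledown_format_error")
    }
  }
  bad <- !is.na(onset) & onset <= start
  if (any(bad)) {
    stop_settledown(
      sprintf("settling_start must precede reported_sleep_onset (row %d)",
              which(bad)[1L]),
      "settledown_format_error"
    )
  }
  data.frame(child_id = df$child_id, night_date = night_date,
             settling_start = start, reported_sleep_onset = onset,
             stringsAsFactors = FALSE)
}

#' Write a sleep-diary CSV
#'
#' @param diary diary data frame as returned by [read_diary_csv()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(diary, path) {
  onset <- ifelse(is.na(diary$reported_sleep_onset), "",
                  format(diary$reported_sleep_onset, "%H:%M", tz = "UTC"))
  out <- data.frame(
    child_id = diary$child_id,
    night_date = as.character(diary$night_date),
    settling_start = format(diary$settling_start, "%H:%M", tz = "UTC"),
    reported_sleep_onset = onset,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labels CSV
#'
#' Dialect: `child_id,group,age_years,sex` with `group` one of `SS`/`NSS` and
#' `sex` one of `M`/`F`.
#'
#' @param path file path.
#' @return data frame of child records.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        strip.white = TRUE)
  need <- c("child_id", "group", "age_years", "sex")
  if (!all(need %in% names(df))) {
    stop_settledown(
      sprintf("labels CSV must have columns %s", paste(need, collapse = ", ")),
      "settledown_format_error"
    )
  }
  if (!all(df$group %in% c("SS", "NSS"))) {
    stop_settledown(sprintf("unknown group label '%s'",
                            setdiff(df$group, c("SS", "NSS"))[1L]),
                    "settledown_format_error")
  }
  if (!all(df$sex %in% c("M", "F"))) {
    stop_settledown(sprintf("unknown sex code '%s'",
                            setdiff(df$sex, c("M", "F"))[1L]),
                    "settledown_format_error")
  }
  if (anyDuplicated(df$child_id)) {
    stop_settledown("duplicated child_id in labels", "settledown_format_error")
  }
  df[, need]
}

#' Write a labels CSV
#'
#' @param labels child-record data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(labels[, c("child_id", "group", "age_years", "sex")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a cohort dataset
#'
#' Bundles per-child activity series, diary entries and group labels into one
#' validated container keyed by child.
#'
#' @param series list of [activity_series()] objects.
#' @param diary diary data frame ([read_diary_csv()] dialect).
#' @param labels child-record data frame ([read_labels_csv()] dialect).
#' @return An object of class `cohort_dataset`: a list with elements `labels`,
#'   `series` (named by child) and `diary`.
#' @export
assemble_dataset <- function(series, diary, labels) {
  ids <- vapply(series, function(s) s$child_id, character(1))
  if (anyDuplicated(ids)) {
    stop_settledown("more than one activity series for one child",
                    "settledown_assembly_error")
  }
  orphan <- setdiff(c(ids, unique(diary$child_id)), labels$child_id)
  if (length(orphan)) {
    stop_settledown(sprintf("child_id '%s' has no labels entry", orphan[1L]),
                    "settledown_assembly_error")
  }
  names(series) <- ids
  structure(list(labels = labels, series = series, diary = diary),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  nights <- table(factor(x$diary$child_id, levels = x$labels$child_id))
  cat(sprintf("<cohort_dataset> %d children (%d SS / %d NSS), %d diary nights\n",
              nrow(x$labels), sum(x$labels$group == "SS"),
              sum(x$labels$group == "NSS"), nrow(x$diary)))
  cat(sprintf("  diary nights per child: median %g, range %d-%d\n",
              stats::median(as.numeric(nights)), min(nights), max(nights)))
  invisible(x)
}
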