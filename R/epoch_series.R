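#' Construct an epoch-count series
#'
#' The unit of all processing: a device-stamped, fixed-epoch integer count
#' time series as produced by a legacy uniaxial Actigraph monitor. All clock
#' arithmetic is done on the naive local clock of the device: datetimes are
#' stored as `POSIXct` in the `"UTC"` zone purely as a zone-free container,
#' and daylight-saving events are handled explicitly by [adjust_dst()] from
#' per-study event dates rather than from a timezone database.
#'
#' @param counts Integer vector of epoch counts, temporal order. Must be
#'   non-negative. For raw (non-reintegrated) series the device saturates at
#'   32767; larger values raise a warning (classification of such files is the
#'   cleaning module's job, not the constructor's).
#' @param start_datetime `POSIXct` (naive clock) or a string
#'   `"YYYY-mm-dd HH:MM:SS"`; timestamp of the first epoch.
#' @param epoch_length Epoch length in seconds: 60, or a positive divisor of
#'   60 for sub-minute data awaiting reintegration.
#' @param serial_number,device_model Device identity; `device_model` is one of
#'   `"7164"`, `"71256"`, `"GT1M"`, `"unknown"`.
#' @param study_id,participant_id,wave Study bookkeeping strings.
#' @param file_label File label (filename stem) used for duplicate resolution
#'   and start-time exception matching.
#' @param dst_events Data frame of daylight-saving events relevant to this
#'   recording, columns `event_datetime` (`POSIXct`) and `direction`
#'   (`"spring_forward"` or `"fall_back"`); may be empty.
#' @param reintegrated Logical; `TRUE` once sub-minute counts have been summed
#'   to 60 s (the saturation ceiling no longer applies).
#'
#' @return An object of class `epoch_series`.
#' @seealso [epoch_timestamps()], [read_count_file()], [reintegrate()]
#' @export
epoch_series <- function(counts, start_datetime, epoch_length = 60L,
                         serial_number = "UNKNOWN", device_model = "unknown",
                         study_id = "", participant_id = "", wave = "1",
                         file_label = "", dst_events = NULL,
                         reintegrated = FALSE) {
  if (is.character(start_datetime)) {
    start_datetime <- as.POSIXct(start_datetime, tz = "UTC")
  }
  stopifnot(inherits(start_datetime, "POSIXct"), length(start_datetime) == 1L,
            !is.na(start_datetime))
  attr(start_datetime, "tzone") <- "UTC"
  epoch_length <- as.integer(epoch_length)
  if (is.na(epoch_length) || epoch_length < 1L || epoch_length > 60L ||
      60L %% epoch_length != 0L) {
    stop("epoch_length must be a positive divisor of 60 (seconds), got: ",
         epoch_length)
  }
  device_model <- match.arg(device_model, c("7164", "71256", "GT1M", "unknown"))
  counts <- as_count_vector(counts)
  if (!reintegrated && any(counts > 32767L)) {
    warning("counts exceed the 32767 device saturation ceiling; ",
            "file is a flag candidate")
  }
  if (is.null(dst_events)) {
    dst_events <- data.frame(
      event_datetime = as.POSIXct(character(), tz = "UTC"),
      direction = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(counts = counts, start_datetime = start_datetime,
         epoch_length = epoch_length, serial_number = as.character(serial_number),
         device_model = device_model, study_id = as.character(study_id),
         participant_id = as.character(participant_id), wave = as.character(wave),
         file_label = as.character(file_label), dst_events = dst_events,
         reintegrated = isTRUE(reintegrated)),
    class = "epoch_series")
}

# strict integer coercion: rejects negatives, NAs and non-integer numerics
as_count_vector <- function(counts) {
  if (is.double(counts)) {
    if (any(is.na(counts)) || any(counts != floor(counts))) {
      stop("counts must be integers")
    }
    counts <- as.integer(counts)
  }
  counts <- as.integer(counts)
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0L)) stop("counts must be non-negative")
  counts
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %s | model %s | serial %s\n",
              x$file_label, x$device_model, x$serial_number))
  cat(sprintf("  start %s, epoch %d s, %d epochs (%.1f days)\n",
              format(x$start_datetime, "%Y-%m-%d %H:%M:%S"),
              x$epoch_length, length(x$counts),
              length(x$counts) * x$epoch_length / 86400))
  invisible(x)
}

#' Number of epochs in a series
#' @param series An [epoch_series()].
#' @return Integer epoch count.
#' @export
n_epochs <- function(series) length(series$counts)

#' Timestamps of every epoch
#'
#' Epoch `i` (1-based) starts at `start_datetime + (i - 1) * epoch_length`;
#' timestamps are always derived, never stored.
#'
#' @param series An [epoch_series()].
#' @return `POSIXct` vector, one entry per epoch.
#' @export
epoch_timestamps <- function(series) {
  series$start_datetime +
    (seq_along(series$counts) - 1L) * series$epoch_length
}

#' File identity key
#'
#' Keys a file for duplicate resolution and exception matching as
#' `study|participant|wave|serial|label`. The key components were chosen so
#' that two monitors worn by the same participant in the same wave collide on
#' the participant portion but remain distinguishable by serial/label.
#'
#' @param series An [epoch_series()].
#' @return A single string.
#' @export
file_key <- function(series) {
  paste(series$study_id, series$participant_id, series$wave,
        series$serial_number, series$file_label, sep = "|")
}

#' Participant-level grouping key (drops serial and label)
#' @param series An [epoch_series()].
#' @return A single string.
#' @export
participant_key <- function(series) {
  paste(series$study_id, series$participant_id, series$wave, sep = "|")
}

# minute-of-day (0..1439) of each epoch; requires 60-s epochs
minute_of_day <- function(series) {
  stopifnot(series$epoch_length == 60L)
  t0 <- as.POSIXlt(series$start_datetime, tz = "UTC")
  start_min <- t0$hour * 60L + t0$min
  (start_min + seq_along(series$counts) - 1L) %% 1440L
}

# calendar date (Date) of each epoch; requires 60-s epochs
date_of_epoch <- function(series) {
  stopifnot(series$epoch_length == 60L)
  as.Date(epoch_timestamps(series), tz = "UTC")
}

require_minute_epochs <- function(series, what) {
  if (series$epoch_length != 60L) {
    stop(what, " requires 60-s epochs; reintegrate() first (epoch is ",
         series$epoch_length, " s)", call. = FALSE)
  }
  invisible(series)
}
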