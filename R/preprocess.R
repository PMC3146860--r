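#' Reintegrate sub-minute epochs to a longer epoch
#'
#' Studies collected counts at epochs from 5 to 60 s; outcome variables are
#' only comparable at a common resolution, so sub-minute files are summed up
#' ("reintegrated") to 60-s epochs before analysis. Counts are summed over
#' consecutive blocks of `target_epoch / epoch_length` epochs; a trailing
#' partial block is dropped and logged in the provenance. Total counts are
#' conserved exactly up to the dropped tail, and the operation is idempotent
#' at the target epoch.
#'
#' @param series An [epoch_series()].
#' @param target_epoch Target epoch length in seconds (default 60); must be a
#'   multiple of the series' epoch length.
#' @return An [epoch_series()] at `target_epoch`, flagged `reintegrated`.
#' @export
reintegrate <- function(series, target_epoch = 60L) {
  stopifnot(inherits(series, "epoch_series"))
  target_epoch <- as.integer(target_epoch)
  if (target_epoch %% series$epoch_length != 0L) {
    stop("target epoch (", target_epoch, " s) is not a multiple of the ",
         "series epoch (", series$epoch_length, " s)")
  }
  k <- target_epoch %/% series$epoch_length
  if (k == 1L) {
    series$reintegrated <- TRUE
    return(series)
  }
  n <- length(series$counts)
  n_blocks <- n %/% k
  tail_len <- n - n_blocks * k
  kept <- series$counts[seq_len(n_blocks * k)]
  summed <- as.integer(colSums(matrix(kept, nrow = k)))
  out <- series
  out$counts <- summed
  out$epoch_length <- target_epoch
  out$reintegrated <- TRUE
  if (tail_len > 0L) {
    tail_sum <- sum(series$counts[(n_blocks * k + 1L):n])
    out <- add_provenance(out, "dropped_tail", n_blocks * k + 1L, n,
                          sprintf("%d sub-epochs (sum %d) beyond the last full %d-s block",
                                  tail_len, tail_sum, target_epoch))
    out$dropped_tail_sum <- tail_sum
  }
  out
}

#' Declare a daylight-saving event
#'
#' Events are supplied per study from configuration (explicit, auditable
#' dates) rather than inferred from a timezone database, because the pooled
#' studies span hemispheres and years.
#'
#' @param event_datetime Local clock datetime at which clocks change
#'   (`POSIXct` or `"YYYY-mm-dd HH:MM:SS"`). For a spring event this is the
#'   first missing local minute; for a fall event, the first minute of the
#'   repeated span.
#' @param direction `"spring_forward"` or `"fall_back"`.
#' @return One-row data frame usable in `epoch_series(dst_events = )`.
#' @export
dst_event <- function(event_datetime, direction = c("spring_forward", "fall_back")) {
  if (is.character(event_datetime)) {
    event_datetime <- as.POSIXct(event_datetime, tz = "UTC")
  }
  attr(event_datetime, "tzone") <- "UTC"
  data.frame(event_datetime = event_datetime,
             direction = match.arg(direction), stringsAsFactors = FALSE)
}

#' Normalize a recording that spans a daylight-saving event
#'
#' Recordings spanning a clock change would otherwise have one 1380- or
#' 1500-minute day, so all files are adjusted to compare equally:
#'
#' * **spring forward** -- the missing hour is imputed by replicating the 30
#'   minutes immediately preceding the event followed by the 30 minutes
#'   immediately following it; the imputed block is inserted at the event.
#' * **fall back** -- of the 120 device-recorded minutes that map onto the
#'   repeated local hour, only the middle hour (minutes 30--89 of the doubled
#'   span) is retained.
#'
#' After adjustment every complete calendar day again has exactly 1440
#' one-minute epochs. Imputed and collapsed ranges are recorded in the
#' provenance sidecar; imputed epochs are not excluded from any downstream
#' summary.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param event A [dst_event()] row; defaults to the series' own
#'   `dst_events` (each applied in order).
#' @return Adjusted [epoch_series()].
#' @section Boundary handling: If fewer than 30 minutes of data exist before
#'   (or after) a spring event, the available minutes are used and the
#'   shortfall is imputed as zeros, with a warning.
#' @export
adjust_dst <- function(series, event = NULL) {
  require_minute_epochs(series, "adjust_dst()")
  if (is.null(event)) {
    ev <- series$dst_events
    if (is.null(ev) || nrow(ev) == 0L) return(series)
    for (i in seq_len(nrow(ev))) series <- adjust_dst(series, ev[i, , drop = FALSE])
    return(series)
  }
  n <- length(series$counts)
  # epoch index whose timestamp equals the event time (1-based, may be outside)
  idx <- as.integer(round(as.numeric(difftime(event$event_datetime,
                                              series$start_datetime,
                                              units = "mins")))) + 1L
  if (idx < 1L || idx > n) return(series)   # event outside the recording span

  if (event$direction == "spring_forward") {
    pre_n <- min(30L, idx - 1L)
    post_n <- min(30L, n - idx + 1L)
    if (pre_n < 30L || post_n < 30L) {
      warning("spring event within 30 min of a recording boundary; ",
              "shortfall imputed as zeros")
    }
    pre <- c(integer(30L - pre_n),
             if (pre_n > 0L) series$counts[(idx - pre_n):(idx - 1L)] else integer(0))
    post <- c(if (post_n > 0L) series$counts[idx:(idx + post_n - 1L)] else integer(0),
              integer(30L - post_n))
    imputed <- c(pre, post)
    out <- series
    out$counts <- append(series$counts, imputed, after = idx - 1L)
    out <- add_provenance(out, "imputed_spring", idx, idx + 59L,
                          sprintf("inserted 60 min at %s (pre-30 + post-30 replication)",
                                  format(event$event_datetime, "%Y-%m-%d %H:%M")))
  } else {
    # doubled span: 120 device minutes starting at the event map to one local hour
    span_end <- idx + 119L
    if (span_end > n) {
      warning("fall event within 120 min of the recording end; ",
              "retaining what is available")
      span_end <- n
    }
    span <- idx:span_end
    keep_lo <- idx + 30L
    keep_hi <- min(idx + 89L, span_end)
    drop_idx <- setdiff(span, keep_lo:keep_hi)
    out <- series
    out$counts <- series$counts[-drop_idx]
    out <- add_provenance(out, "collapsed_fall", idx, idx + 119L,
                          sprintf("kept middle hour (device minutes %d-%d) of doubled span at %s",
                                  keep_lo, keep_hi,
                                  format(event$event_datetime, "%Y-%m-%d %H:%M")))
  }
  out
}
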