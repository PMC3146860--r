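#' Configuration for file-quality flagging
#'
#' The published flag rules describe symptoms (overnight wear, count
#' plateaus, shifted diurnal timing); their operational thresholds and the
#' adjudication of overnight wear were originally manual. This configuration
#' makes every threshold explicit so classification is deterministic.
#'
#' @param overnight_hours Clock hours (starting hour, 24-h) inspected for
#'   overnight wear; default `c(2, 3, 4)` (i.e. 02:00--05:00).
#' @param overnight_min_minutes Wear minutes within the inspected hours that
#'   trigger the overnight-wear rule (default 10).
#' @param overnight_per_hour If `TRUE` (default) the threshold applies to
#'   each single clock hour ("hour 2, 3 and/or 4"); if `FALSE`, to the sum
#'   across the inspected hours.
#' @param plateau_min_run Minimum run of identical consecutive counts
#'   (default 3).
#' @param plateau_min_value Minimum count value for a plateau (default 10).
#' @param shift_night Night block for the shift symptom, minutes of day
#'   `c(start, end)` half-open (default 00:00--05:00).
#' @param shift_day Day block (default 09:00--18:00).
#' @param shift_night_active_min Nonzero night minutes required per day
#'   (default 30).
#' @param shift_day_nonwear_min Non-wear minutes inside the day block
#'   required per day (default 180). Non-wear is judged by the wear mask, so
#'   the long daytime zero runs of a shifted file are recognized even when
#'   they contain the interruption minutes the wear rule tolerates.
#' @param shift_template Diurnal template for lag estimation: numeric vector
#'   of length 1440, or `NULL` for the default trapezoidal day-active
#'   profile (active over the 07:00--22:00 waking day with half-hour ramps
#'   on each side). Supply a study-specific template when the population's
#'   waking day differs.
#' @param nbr_night_hours Clock hours inspected for a non-return-to-baseline
#'   floor (default `0:5`).
#' @param nbr_min_consecutive_hours Consecutive fully-nonzero night hours,
#'   on every monitored night, that constitute a floor (default 3). This
#'   numeric criterion is this implementation's own; the original
#'   adjudication was visual.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(overnight_hours = c(2, 3, 4),
                            overnight_min_minutes = 10L,
                            overnight_per_hour = TRUE,
                            plateau_min_run = 3L, plateau_min_value = 10L,
                            shift_night = c(0L, 300L),
                            shift_day = c(540L, 1080L),
                            shift_night_active_min = 30L,
                            shift_day_nonwear_min = 180L,
                            shift_template = NULL,
                            nbr_night_hours = 0:5,
                            nbr_min_consecutive_hours = 3L) {
  if (is.null(shift_template)) shift_template <- default_diurnal_template()
  stopifnot(length(shift_template) == 1440L)
  structure(list(overnight_hours = as.integer(overnight_hours),
                 overnight_min_minutes = as.integer(overnight_min_minutes),
                 overnight_per_hour = isTRUE(overnight_per_hour),
                 plateau_min_run = as.integer(plateau_min_run),
                 plateau_min_value = as.integer(plateau_min_value),
                 shift_night = as.integer(shift_night),
                 shift_day = as.integer(shift_day),
                 shift_night_active_min = as.integer(shift_night_active_min),
                 shift_day_nonwear_min = as.integer(shift_day_nonwear_min),
                 shift_template = as.numeric(shift_template),
                 nbr_night_hours = as.integer(nbr_night_hours),
                 nbr_min_consecutive_hours = as.integer(nbr_min_consecutive_hours)),
            class = "cleaning_config")
}

# trapezoidal day-active diurnal profile: zero overnight, half-hour ramps
# around a flat 07:00-22:00 waking day (symmetric, so circular correlation
# peaks at the true whole-hour lag for day-active recordings)
default_diurnal_template <- function() {
  m <- seq_len(1440L) - 1L
  tpl <- numeric(1440L)
  tpl[m >= 420L & m < 1320L] <- 1
  ramp_up <- m >= 390L & m < 420L
  tpl[ramp_up] <- (m[ramp_up] - 390L) / 30
  ramp_dn <- m >= 1320L & m < 1350L
  tpl[ramp_dn] <- (1350L - m[ramp_dn]) / 30
  tpl
}

new_evidence <- function(rule_id = character(), start_epoch = integer(),
                         end_epoch = integer(), detail = character()) {
  data.frame(rule_id = rule_id, start_epoch = as.integer(start_epoch),
             end_epoch = as.integer(end_epoch), detail = detail,
             stringsAsFactors = FALSE)
}

#' File flag report
#'
#' One flag per file, precedence-resolved, with the evidence of every rule
#' that fired (including rules outranked by the final flag).
#'
#' @param file_key File identity key (see [file_key()]).
#' @param flag One of `"OK"`, `"SPURIOUS"`, `"TEMPORALLY_SHIFTED"`,
#'   `"CORRUPT"`, `"NO_WEAR"`, `"DUPLICATE_DROPPED"`, `"MISSING_PHENOTYPE"`.
#' @param evidence Data frame with columns `rule_id`, `start_epoch`,
#'   `end_epoch`, `detail`.
#' @return An object of class `flag_report`.
#' @export
flag_report <- function(file_key, flag, evidence = new_evidence()) {
  flag <- match.arg(flag, c("OK", "SPURIOUS", "TEMPORALLY_SHIFTED", "CORRUPT",
                            "NO_WEAR", "DUPLICATE_DROPPED", "MISSING_PHENOTYPE"))
  if (flag == "OK" && nrow(evidence) > 0L) {
    stop("an OK report cannot carry firing rules")
  }
  structure(list(file_key = file_key, flag = flag, evidence = evidence),
            class = "flag_report")
}

#' @export
print.flag_report <- function(x, ...) {
  cat(sprintf("<flag_report> %s: %s (%d evidence rows)\n",
              x$file_key, x$flag, nrow(x$evidence)))
  invisible(x)
}

#' Resolve duplicate files for one participant
#'
#' When two monitors were deployed on the same participant, one file is
#' kept: the non-corrupt one if exactly one is corrupt, otherwise the file
#' with the lexicographically first label. Dropped files are flagged
#' `DUPLICATE_DROPPED` with the winning key in the evidence detail.
#'
#' @param files List of [epoch_series()] sharing a participant key.
#' @param corrupt Logical vector marking files that failed to parse
#'   (default: none). If all files in the group are corrupt, the first label
#'   is kept and flagged `CORRUPT`.
#' @return List with `kept` (one [epoch_series()]), `kept_corrupt`
#'   (logical) and `dropped` (list of [flag_report()]).
#' @export
resolve_duplicates <- function(files, corrupt = NULL) {
  stopifnot(length(files) >= 1L)
  if (is.null(corrupt)) corrupt <- rep(FALSE, length(files))
  stopifnot(length(corrupt) == length(files))
  labels <- vapply(files, function(f) f$file_label, "")
  ord <- order(labels)
  cand <- ord[!corrupt[ord]]
  winner <- if (length(cand)) cand[1] else ord[1]
  dropped <- lapply(setdiff(seq_along(files), winner), function(i) {
    flag_report(file_key(files[[i]]), "DUPLICATE_DROPPED",
                new_evidence("duplicate", 1L, length(files[[i]]$counts),
                             sprintf("dropped in favor of %s",
                                     file_key(files[[winner]]))))
  })
  list(kept = files[[winner]], kept_corrupt = !length(cand), dropped = dropped)
}

#' Detect overnight wear (flag rule 1)
#'
#' Fires when, on any monitored calendar day, wear time within a single
#' inspected night clock hour (02:00--03:00, 03:00--04:00 or 04:00--05:00 by
#' default) reaches the threshold. Overnight wear alone does not make a file
#' spurious; it triggers adjudication among legitimate wear, a temporal
#' shift, and device faults.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param wear Aligned [wear_mask()].
#' @param config A [cleaning_config()].
#' @return Evidence data frame (zero rows if the rule does not fire).
#' @export
detect_overnight_wear <- function(series, wear, config = cleaning_config()) {
  require_minute_epochs(series, "detect_overnight_wear()")
  stopifnot(length(wear) == length(series$counts))
  mod <- minute_of_day(series)
  dates <- date_of_epoch(series)
  hr <- mod %/% 60L
  sel <- hr %in% config$overnight_hours
  ev <- new_evidence()
  if (!any(sel)) return(ev)
  w <- as.logical(wear)[sel]
  if (config$overnight_per_hour) {
    grp <- interaction(dates[sel], hr[sel], drop = TRUE)
  } else {
    grp <- interaction(dates[sel], drop = TRUE)
  }
  mins <- tapply(w, grp, sum)
  fired <- names(mins)[mins >= config$overnight_min_minutes]
  for (g in fired) {
    idx <- which(sel)[grp == g]
    ev <- rbind(ev, new_evidence(
      "overnight_wear", min(idx), max(idx),
      sprintf("%d wear min in night block %s", mins[[g]], g)))
  }
  ev
}

#' Detect count plateaus (flag rule 2)
#'
#' Returns every maximal run of at least `plateau_min_run` identical
#' consecutive counts at a value of at least `plateau_min_value`; such
#' plateaus indicate technical faults, occurring most often at the 32767
#' saturation ceiling (runs at 32767 are tagged `saturation`).
#'
#' @param series An [epoch_series()].
#' @param config A [cleaning_config()].
#' @return Data frame with columns `start_index`, `length`, `value`,
#'   `saturation` (zero rows when no plateau exists).
#' @export
detect_plateaus <- function(series, config = cleaning_config()) {
  r <- rle(series$counts)
  keep <- r$lengths >= config$plateau_min_run &
    r$values >= config$plateau_min_value
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  data.frame(start_index = starts[keep], length = r$lengths[keep],
             value = r$values[keep], saturation = r$values[keep] == 32767L,
             row.names = NULL)
}

plateau_evidence <- function(plateaus) {
  if (nrow(plateaus) == 0L) return(new_evidence())
  new_evidence("plateau", plateaus$start_index,
               plateaus$start_index + plateaus$length - 1L,
               ifelse(plateaus$saturation,
                      sprintf("saturation plateau (32767) x %d", plateaus$length),
                      sprintf("plateau at %d x %d", plateaus$value,
                              plateaus$length)))
}

# per-full-day minute matrix (rows = days with 1440 monitored minutes) of
# an arbitrary per-epoch vector
full_day_matrix <- function(series, x = series$counts) {
  dates <- date_of_epoch(series)
  full <- names(which(table(dates) == 1440L))
  if (!length(full)) return(NULL)
  keep <- dates %in% as.Date(full)
  matrix(x[keep], ncol = 1440L, byrow = TRUE)
}

#' Detect a temporally shifted file
#'
#' A temporally shifted file has its time stamping offset by a whole number
#' of hours, producing activity counts during the night and long zero runs
#' during the day on *every* monitored day. The detector requires at least
#' two complete days; it fires only when every complete day shows both
#' symptoms (night activity above `shift_night_active_min` nonzero minutes,
#' and at least `shift_day_nonwear_min` non-wear minutes inside the day
#' block). The shift size is estimated as the circular lag (in whole
#' hours) maximizing the correlation between the mean diurnal count profile
#' and the configured template profile.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param wear Aligned [wear_mask()] (non-wear minutes are excluded from the
#'   night-activity symptom).
#' @param config A [cleaning_config()].
#' @return List with `shifted` (logical), `estimated_shift_hours` (integer
#'   or `NA`), `evidence` (data frame).
#' @export
detect_temporal_shift <- function(series, wear, config = cleaning_config()) {
  require_minute_epochs(series, "detect_temporal_shift()")
  mat <- full_day_matrix(series)
  if (is.null(mat) || nrow(mat) < 2L) {
    return(list(shifted = FALSE, estimated_shift_hours = NA_integer_,
                evidence = new_evidence("temporal_shift", NA_integer_,
                                        NA_integer_,
                                        "insufficient data (<2 complete days)")))
  }
  stopifnot(length(wear) == length(series$counts))
  wmat <- full_day_matrix(series, as.logical(wear))
  night <- (config$shift_night[1] + 1L):config$shift_night[2]
  daybk <- (config$shift_day[1] + 1L):config$shift_day[2]
  night_active <- apply(mat[, night, drop = FALSE], 1L,
                        function(x) sum(x > 0L))
  day_nonwear <- apply(wmat[, daybk, drop = FALSE], 1L,
                       function(w) sum(!w))
  all_fire <- all(night_active >= config$shift_night_active_min) &&
    all(day_nonwear >= config$shift_day_nonwear_min)
  if (!all_fire) {
    return(list(shifted = FALSE, estimated_shift_hours = NA_integer_,
                evidence = new_evidence()))
  }
  profile <- colMeans(mat)
  tpl <- config$shift_template
  lags <- 0:23
  cors <- vapply(lags, function(k) {
    rot <- tpl[((seq_len(1440L) - 1L - k * 60L) %% 1440L) + 1L]
    suppressWarnings(stats::cor(profile, rot))
  }, 0)
  cors[is.na(cors)] <- -Inf
  est <- lags[which.max(cors)]
  list(shifted = TRUE, estimated_shift_hours = as.integer(est),
       evidence = new_evidence(
         "temporal_shift", 1L, length(series$counts),
         sprintf("night activity + daytime zero runs on all %d complete days; estimated shift +%d h",
                 nrow(mat), est)))
}

#' Detect a non-return-to-baseline floor
#'
#' A potentially spurious device that no longer returns to baseline (zero)
#' shows a constant-like nonzero floor through the night. Detected here as a
#' span of at least `nbr_min_consecutive_hours` consecutive night clock
#' hours whose minutes are all nonzero, on every monitored night; the
#' numeric criterion is this implementation's own stand-in for the original
#' visual adjudication.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param config A [cleaning_config()].
#' @return Evidence data frame (zero rows if not detected).
#' @export
detect_no_baseline_return <- function(series, config = cleaning_config()) {
  require_minute_epochs(series, "detect_no_baseline_return()")
  mat <- full_day_matrix(series)
  if (is.null(mat)) return(new_evidence())
  per_day <- apply(mat, 1L, function(day) {
    hr_all_nonzero <- vapply(config$nbr_night_hours, function(h) {
      all(day[(h * 60L + 1L):(h * 60L + 60L)] > 0L)
    }, TRUE)
    r <- rle(hr_all_nonzero)
    any(r$values & r$lengths >= config$nbr_min_consecutive_hours)
  })
  if (!all(per_day)) return(new_evidence())
  new_evidence("no_baseline_return", 1L, length(series$counts),
               sprintf("nonzero night floor (>=%d consecutive all-nonzero night hours) on all %d complete days",
                       config$nbr_min_consecutive_hours, nrow(mat)))
}

#' Classify a file
#'
#' Applies every automated flag rule and resolves one flag by precedence
#' `CORRUPT > NO_WEAR > TEMPORALLY_SHIFTED > SPURIOUS > OK` (corrupt files
#' never reach this function -- they fail parsing upstream). `NO_WEAR` fires
#' when the file has zero wear minutes. `SPURIOUS` fires on plateau evidence
#' or when overnight wear is attributed to a non-return-to-baseline floor.
#' The report carries the evidence of all fired rules, including those
#' outranked by the final flag. Classification is a pure function of its
#' arguments.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param wear Aligned [wear_mask()]; computed with [detect_nonwear()] when
#'   omitted.
#' @param config A [cleaning_config()].
#' @return A [flag_report()].
#' @export
classify_file <- function(series, wear = NULL, config = cleaning_config()) {
  require_minute_epochs(series, "classify_file()")
  if (is.null(wear)) wear <- detect_nonwear(series)
  ev <- new_evidence()
  if (sum(wear) == 0L) {
    ev <- rbind(ev, new_evidence("no_wear", 1L, length(series$counts),
                                 "zero wear minutes"))
  }
  overnight <- detect_overnight_wear(series, wear, config)
  plateaus <- plateau_evidence(detect_plateaus(series, config))
  shift <- detect_temporal_shift(series, wear, config)
  nbr <- detect_no_baseline_return(series, config)
  ev <- rbind(ev, overnight, plateaus, if (shift$shifted) shift$evidence, nbr)
  flag <- if (any(ev$rule_id == "no_wear")) "NO_WEAR"
  else if (shift$shifted) "TEMPORALLY_SHIFTED"
  else if (nrow(plateaus) > 0L ||
           (nrow(overnight) > 0L && nrow(nbr) > 0L)) "SPURIOUS"
  else "OK"
  if (flag == "OK") ev <- new_evidence()   # informational-only evidence: none fired
  report <- flag_report(file_key(series), flag, ev)
  report$estimated_shift_hours <- shift$estimated_shift_hours
  report
}

#' Write flag reports as delimited text
#'
#' @param reports List of [flag_report()].
#' @param path Output path (tab-separated).
#' @return Data frame written, invisibly.
#' @export
write_flag_report <- function(reports, path) {
  rows <- lapply(reports, function(r) {
    if (nrow(r$evidence) == 0L) {
      data.frame(file_key = r$file_key, flag = r$flag, rule_id = "",
                 start_epoch = NA_integer_, end_epoch = NA_integer_,
                 detail = "", stringsAsFactors = FALSE)
    } else {
      cbind(data.frame(file_key = r$file_key, flag = r$flag,
                       stringsAsFactors = FALSE), r$evidence)
    }
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
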