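#' Define an intensity cutpoint set
#'
#' A cutpoint set partitions the per-minute count axis `[0, Inf)` into the
#' contiguous, exhaustive intensity categories sedentary, light, moderate
#' and vigorous. Intervals are lower-bound inclusive: a minute whose count
#' equals a category's lower boundary belongs to that category.
#'
#' @param name Short identifier (used as a column prefix in summaries).
#' @param light,moderate,vigorous Lower boundaries (counts per minute) of
#'   the light, moderate and vigorous categories; strictly increasing.
#'   Sedentary is `[0, light)`.
#' @param age_range Optional two-element numeric, years.
#' @param citation Free-text provenance of the thresholds.
#' @return Object of class `cutpoint_set`.
#' @export
cutpoint_set <- function(name, light, moderate, vigorous,
                         age_range = NULL, citation = "") {
  b <- c(0, light, moderate, vigorous)
  if (any(diff(b) <= 0)) stop("cutpoint boundaries must be strictly increasing")
  structure(list(name = name, boundaries = b,
                 categories = c("sedentary", "light", "moderate", "vigorous"),
                 age_range = age_range, citation = citation),
            class = "cutpoint_set")
}

#' @export
print.cutpoint_set <- function(x, ...) {
  cat(sprintf("<cutpoint_set> %s: sed <%g | light %g-%g | mod %g-%g | vig >=%g\n",
              x$name, x$boundaries[2], x$boundaries[2], x$boundaries[3] - 1,
              x$boundaries[3], x$boundaries[4] - 1, x$boundaries[4]))
  invisible(x)
}

#' Built-in cutpoint registry
#'
#' A named list of widely used child/adolescent Actigraph cutpoint sets.
#' The registry is configuration, not a fixed truth: studies add entries as
#' the field evolves, and every summary column is prefixed with the set
#' name so multiple sets coexist in one output table.
#'
#' @param sets Optional character vector selecting a subset by name.
#' @return Named list of [cutpoint_set()] objects.
#' @export
cutpoint_registry <- function(sets = NULL) {
  reg <- list(
    evenson = cutpoint_set("evenson", 100, 2296, 4012,
                           age_range = c(5, 18),
                           citation = "Evenson et al. 2008, J Sports Sci 26:1557-65"),
    puyau = cutpoint_set("puyau", 800, 3200, 8200,
                         age_range = c(6, 16),
                         citation = "Puyau et al. 2002, Obes Res 10:150-7"),
    mattocks = cutpoint_set("mattocks", 100, 3581, 6130,
                            age_range = c(11, 13),
                            citation = "Mattocks et al. 2007, J Phys Act Health 4:S98-111"))
  if (!is.null(sets)) {
    missing <- setdiff(sets, names(reg))
    if (length(missing)) stop("unknown cutpoint set(s): ",
                              paste(missing, collapse = ", "))
    reg <- reg[sets]
  }
  reg
}

#' Define a clock time window
#'
#' Windows are half-open `[start, end)` on the local clock and may wrap
#' midnight. A minute belongs to a window iff its start timestamp falls
#' inside it.
#'
#' @param label Window name (column prefix in summaries).
#' @param start,end Clock times as `"HH:MM"` strings or minute-of-day
#'   integers (0--1439); `start != end`.
#' @return One-row data frame with `label`, `start_min`, `end_min`.
#' @export
time_window <- function(label, start, end) {
  to_min <- function(x) {
    if (is.character(x)) {
      p <- as.integer(strsplit(x, ":")[[1]])
      p[1] * 60L + p[2]
    } else as.integer(x)
  }
  s <- to_min(start); e <- to_min(end)
  stopifnot(s >= 0L, s < 1440L, e >= 0L, e <= 1440L)
  if (s == e %% 1440L) stop("window start and end must differ")
  data.frame(label = label, start_min = s, end_min = e,
             stringsAsFactors = FALSE)
}

#' The 24 on-the-hour windows hr1..hr24
#' @return Data frame of 24 [time_window()] rows, hr1 = `[00:00, 01:00)`.
#' @export
hourly_windows <- function() {
  do.call(rbind, lapply(1:24, function(h) {
    time_window(sprintf("hr%d", h), (h - 1L) * 60L, h * 60L)
  }))
}

#' Label each minute with an intensity category
#'
#' Wear minutes are labeled by the cutpoint category whose interval contains
#' their count; non-wear minutes are labeled `nonwear` and excluded from all
#' totals (a non-wear zero is never sedentary time).
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param mask Aligned [wear_mask()].
#' @param cutpoints A [cutpoint_set()].
#' @return Factor vector with levels sedentary, light, moderate, vigorous,
#'   nonwear.
#' @export
classify_intensity <- function(series, mask, cutpoints) {
  require_minute_epochs(series, "classify_intensity()")
  stopifnot(inherits(cutpoints, "cutpoint_set"),
            length(mask) == length(series$counts))
  idx <- findInterval(series$counts, cutpoints$boundaries)  # 1..4, lower-inclusive
  labels <- cutpoints$categories[idx]
  labels[!as.logical(mask)] <- "nonwear"
  factor(labels, levels = c(cutpoints$categories, "nonwear"))
}

#' Bout-accumulated minutes
#'
#' A bout is a maximal run of consecutive minutes at or above the target
#' intensity, with zero tolerated interruption minutes by default; non-wear
#' always breaks a bout. Each bout's full duration accrues to the bin
#' containing it; with the default bins, minutes from bouts shorter than 10
#' minutes land in `[1,10)` and bouts of 10 minutes or longer land in
#' `[10, Inf)`.
#'
#' @param labels Factor from [classify_intensity()].
#' @param target Intensity categories counting toward the bout (default
#'   MVPA, i.e. moderate or vigorous).
#' @param bins Lower edges of the duration bins in minutes (default
#'   `c(1, 10)`).
#' @param tolerance Interruption minutes tolerated inside a bout (default 0,
#'   the strictest reading; interruption minutes never accrue to the bout).
#' @return Named numeric vector of minutes per bin (names like `"1-9min"`,
#'   `"10+min"`).
#' @export
bout_minutes <- function(labels, target = c("moderate", "vigorous"),
                         bins = c(1, 10), tolerance = 0L) {
  in_target <- labels %in% target
  runs <- bout_runs(in_target, labels != "nonwear", tolerance)
  bin_names <- c(paste0(bins[-length(bins)], "-", bins[-1] - 1, "min"),
                 paste0(bins[length(bins)], "+min"))
  out <- stats::setNames(numeric(length(bins)), bin_names)
  for (len in runs) {
    b <- findInterval(len, bins)
    if (b >= 1L) out[b] <- out[b] + len
  }
  out
}

# lengths of maximal target runs; `tolerance` nonwear/other minutes may be
# bridged inside a bout but do not count toward its length
bout_runs <- function(in_target, is_wear, tolerance = 0L) {
  if (tolerance == 0L) {
    r <- rle(in_target)
    return(r$lengths[r$values])
  }
  # tolerant variant: merge target runs separated by <= tolerance wear
  # minutes of non-target activity (nonwear still breaks bouts)
  r <- rle(ifelse(!is_wear, 2L, as.integer(in_target)))  # 0 other, 1 target, 2 nonwear
  lens <- integer(0)
  cur <- 0L
  for (i in seq_along(r$values)) {
    v <- r$values[i]; l <- r$lengths[i]
    if (v == 1L) {
      cur <- cur + l
    } else if (v == 0L && l <= tolerance && cur > 0L &&
               i < length(r$values) && r$values[i + 1L] == 1L) {
      # bridged interruption: bout continues, interruption not counted
    } else {
      if (cur > 0L) lens <- c(lens, cur)
      cur <- 0L
    }
  }
  if (cur > 0L) lens <- c(lens, cur)
  lens
}

#' Per-window wear and intensity minutes
#'
#' Assigns each minute to every window whose `[start, end)` span contains
#' its start timestamp (custom windows may overlap; a minute can count in
#' several). The 24 hourly windows partition each day exactly.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param mask Aligned [wear_mask()].
#' @param labels Factor from [classify_intensity()].
#' @param windows Data frame of [time_window()] rows (default
#'   [hourly_windows()]).
#' @return Data frame: one row per monitored day per window with wear and
#'   per-intensity minutes.
#' @export
window_summaries <- function(series, mask, labels, windows = hourly_windows()) {
  require_minute_epochs(series, "window_summaries()")
  mod <- minute_of_day(series)
  dates <- date_of_epoch(series)
  mask <- as.logical(mask)
  res <- list()
  for (w in seq_len(nrow(windows))) {
    s <- windows$start_min[w]; e <- windows$end_min[w]
    inw <- if (s < e) mod >= s & mod < e else mod >= s | mod < e
    for (d in unique(dates)) {
      sel <- inw & dates == d
      res[[length(res) + 1L]] <- data.frame(
        date = as.Date(d, origin = "1970-01-01"),
        window = windows$label[w],
        monitored_minutes = sum(sel),
        wear_minutes = sum(mask[sel]),
        sedentary = sum(labels[sel] == "sedentary"),
        light = sum(labels[sel] == "light"),
        moderate = sum(labels[sel] == "moderate"),
        vigorous = sum(labels[sel] == "vigorous"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Summarize one file into per-day outcome rows
#'
#' Produces one row per monitored calendar day with wear time, mean counts
#' per wear minute, per-cutpoint-set intensity minutes, MVPA bout-bin
#' minutes, and validity flags at each wear criterion. Intensity minutes
#' partition wear minutes within every cutpoint set; bout-bin minutes sum to
#' that set's MVPA minutes; changing the cutpoint set never changes wear
#' minutes.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param mask Aligned [wear_mask()]; computed via [detect_nonwear()] when
#'   omitted.
#' @param registry Named list of [cutpoint_set()]s (default
#'   [cutpoint_registry()]).
#' @param windows Optional data frame of [time_window()] rows; when given,
#'   the per-window table is attached as `attr(, "windows")` (per cutpoint
#'   set named in `window_sets`, default the first registry entry).
#' @param criteria Valid-day wear criteria in hours (default `c(8, 10, 12)`).
#' @param window_sets Names of registry entries to expand over windows.
#' @return Data frame of class `day_summary`, one row per day.
#' @export
summarize_day <- function(series, mask = NULL, registry = cutpoint_registry(),
                          windows = NULL, criteria = c(8, 10, 12),
                          window_sets = names(registry)[1]) {
  require_minute_epochs(series, "summarize_day()")
  if (is.null(mask)) mask <- detect_nonwear(series)
  stopifnot(length(mask) == length(series$counts))
  dates <- date_of_epoch(series)
  base <- day_wear(series, mask)
  lmask <- as.logical(mask)
  # mean counts over wear minutes only (exact integer total / wear minutes)
  total_wear_counts <- tapply(series$counts * lmask, dates, sum)
  base$total_counts <- as.integer(total_wear_counts)
  base$counts_per_wear_minute <- ifelse(base$wear_minutes > 0,
                                        base$total_counts / base$wear_minutes,
                                        NA_real_)
  for (cs in registry) {
    labels <- classify_intensity(series, mask, cs)
    for (cat in cs$categories) {
      base[[paste0(cs$name, "_", cat)]] <-
        as.integer(tapply(labels == cat, dates, sum))
    }
    base[[paste0(cs$name, "_mvpa")]] <-
      base[[paste0(cs$name, "_moderate")]] + base[[paste0(cs$name, "_vigorous")]]
    # MVPA bout bins, per day
    bb <- t(vapply(split(seq_along(labels), dates), function(idx) {
      bout_minutes(labels[idx])
    }, c(`1-9min` = 0, `10+min` = 0)))
    base[[paste0(cs$name, "_mvpa_bouts_1_9")]] <- as.numeric(bb[, 1])
    base[[paste0(cs$name, "_mvpa_bouts_10plus")]] <- as.numeric(bb[, 2])
  }
  vd <- valid_days(base[, c("date", "wear_minutes", "monitored_minutes")],
                   criterion_hours = criteria)
  for (h in criteria) {
    base[[sprintf("valid_%gh", h)]] <- vd$per_day[[sprintf("valid_%gh", h)]]
  }
  base <- cbind(data.frame(file_key = file_key(series),
                           study_id = series$study_id,
                           participant_id = series$participant_id,
                           wave = series$wave, stringsAsFactors = FALSE),
                base)
  if (!is.null(windows)) {
    wtabs <- lapply(window_sets, function(nm) {
      labels <- classify_intensity(series, mask, registry[[nm]])
      cbind(cutpoints = nm,
            window_summaries(series, mask, labels, windows))
    })
    attr(base, "windows") <- do.call(rbind, wtabs)
  }
  class(base) <- c("day_summary", class(base))
  base
}

#' Data dictionary for a per-day summary table
#'
#' Emitted alongside every summary export so column semantics (units,
#' interval conventions) travel with the data.
#'
#' @param summaries A `day_summary` data frame.
#' @param registry The cutpoint registry used to build it.
#' @return Data frame with `column`, `description`.
#' @export
data_dictionary <- function(summaries, registry = cutpoint_registry()) {
  desc <- c(
    file_key = "file identity key (study|participant|wave|serial|label)",
    study_id = "contributing study identifier",
    participant_id = "participant identifier within study",
    wave = "measurement wave",
    date = "monitored calendar day (local clock, midnight to midnight)",
    wear_minutes = "wear minutes in day (non-wear rule: >=60 min zeros, <=2 interruption min)",
    monitored_minutes = "minutes of the day covered by the recording",
    total_counts = "sum of counts over wear minutes",
    counts_per_wear_minute = "total_counts / wear_minutes")
  out <- data.frame(column = names(summaries), stringsAsFactors = FALSE)
  out$description <- desc[out$column]
  for (cs in registry) {
    b <- cs$boundaries
    ints <- c(sprintf("[0,%g)", b[2]), sprintf("[%g,%g)", b[2], b[3]),
              sprintf("[%g,%g)", b[3], b[4]), sprintf("[%g,Inf)", b[4]))
    for (i in seq_along(cs$categories)) {
      col <- paste0(cs$name, "_", cs$categories[i])
      out$description[out$column == col] <-
        sprintf("wear minutes with count in %s cpm (%s; lower bound inclusive)",
                ints[i], cs$citation)
    }
    out$description[out$column == paste0(cs$name, "_mvpa")] <-
      "moderate + vigorous minutes"
    out$description[out$column == paste0(cs$name, "_mvpa_bouts_1_9")] <-
      "MVPA minutes accrued in bouts of 1-9 min (zero-tolerance runs)"
    out$description[out$column == paste0(cs$name, "_mvpa_bouts_10plus")] <-
      "MVPA minutes accrued in bouts of >=10 min"
  }
  crit <- grep("^valid_", out$column)
  out$description[crit] <- sprintf(
    "day valid at the >=%s wear criterion (inclusive)",
    sub("valid_", "", out$column[crit]))
  out$description[is.na(out$description)] <- ""
  out
}
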