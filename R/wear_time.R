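#' Wear mask constructor
#'
#' Per-epoch wear/non-wear labels aligned to an [epoch_series()]. Non-wear
#' zeros receive special coding so they can be separated and excluded from
#' the legitimate zeros that occur during sedentary behavior.
#'
#' @param wear Logical vector, `TRUE` = worn.
#' @return Logical vector of class `wear_mask`.
#' @export
wear_mask <- function(wear) {
  stopifnot(is.logical(wear), !anyNA(wear))
  structure(wear, class = "wear_mask")
}

#' @export
print.wear_mask <- function(x, ...) {
  cat(sprintf("<wear_mask> %d min: %d wear, %d nonwear\n",
              length(x), sum(x), sum(!x)))
  invisible(x)
}

# core zero-run scanner on a single unbroken segment of per-minute counts.
# A window [i, j] (zero endpoints) qualifies when j - i + 1 >= min_window and
# it contains at most max_interruptions nonzero interior minutes; the union
# of all qualifying windows is marked nonwear. Only the start of each maximal
# zero run needs scanning: any qualifying window is contained in the maximal
# window anchored at its run start.
nonwear_segment <- function(counts, min_window, max_interruptions) {
  n <- length(counts)
  nonwear <- logical(n)
  zero <- which(counts == 0L)
  if (!length(zero)) return(nonwear)
  nz <- which(counts != 0L)
  run_starts <- zero[c(TRUE, diff(zero) > 1L)]
  for (i in run_starts) {
    k <- findInterval(i, nz)            # nonzeros at or before i
    limit <- if (length(nz) >= k + max_interruptions + 1L) {
      nz[k + max_interruptions + 1L] - 1L
    } else n
    j_max <- zero[findInterval(limit, zero)]
    if (j_max - i + 1L >= min_window) nonwear[i:j_max] <- TRUE
  }
  nonwear
}

#' Segment a minute series into wear and non-wear
#'
#' The monitor is considered not worn wherever a period of at least
#' `min_window` (default 60) minutes of consecutive zeros is encountered,
#' allowing up to `max_interruptions` (default 2) minutes of nonzero
#' interruptions inside the period. A qualifying period must begin and end on
#' a zero minute (a lone spike cannot extend non-wear), interruption minutes
#' inside it are themselves labeled non-wear, and overlapping qualifying
#' periods are unioned. All remaining epochs are wear.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param min_window Minimum period length in minutes.
#' @param max_interruptions Maximum nonzero interruption minutes tolerated
#'   inside a period.
#' @param interruption_cap Per-minute count cap for a nonzero minute to count
#'   as an interruption (default `Inf`, i.e. any nonzero value qualifies; a
#'   finite cap is available for sensitivity analyses). Minutes above the cap
#'   can never lie inside a non-wear period.
#' @return A [wear_mask()] aligned to `series`.
#' @export
detect_nonwear <- function(series, min_window = 60L, max_interruptions = 2L,
                           interruption_cap = Inf) {
  require_minute_epochs(series, "detect_nonwear()")
  counts <- series$counts
  n <- length(counts)
  if (is.finite(interruption_cap)) {
    blockers <- which(counts > interruption_cap)
    bounds <- c(0L, blockers, n + 1L)
    nonwear <- logical(n)
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b] + 1L
      hi <- bounds[b + 1L] - 1L
      if (hi - lo + 1L >= min_window) {
        nonwear[lo:hi] <- nonwear_segment(counts[lo:hi], min_window,
                                          max_interruptions)
      }
    }
  } else {
    nonwear <- nonwear_segment(counts, as.integer(min_window),
                               as.integer(max_interruptions))
  }
  wear_mask(!nonwear)
}

#' Exhaustive non-wear oracle
#'
#' Enumerates every candidate window over the raw minute counts -- each pair
#' of zero endpoints spanning at least `min_window` minutes with at most
#' `max_interruptions` nonzero interior minutes -- and marks the union
#' non-wear. Quadratic cost; intended as an independent reference for
#' [detect_nonwear()] on short series, not for production use.
#'
#' @param counts Integer vector of per-minute counts.
#' @param min_window,max_interruptions As in [detect_nonwear()].
#' @return A [wear_mask()].
#' @export
nonwear_oracle <- function(counts, min_window = 60L, max_interruptions = 2L) {
  counts <- as_count_vector(counts)
  wear_mask(!nonwear_oracle_cpp(counts, as.integer(min_window),
                                as.integer(max_interruptions)))
}

#' Per-day wear minutes
#'
#' Days are local-clock calendar days (midnight to midnight). Partial first
#' and last days are reported with their true monitored minutes.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param mask Aligned [wear_mask()].
#' @return Data frame with columns `date`, `wear_minutes`,
#'   `monitored_minutes`, one row per monitored calendar day.
#' @export
day_wear <- function(series, mask) {
  require_minute_epochs(series, "day_wear()")
  stopifnot(length(mask) == length(series$counts))
  dates <- date_of_epoch(series)
  monitored <- as.integer(table(dates))
  wear <- as.integer(tapply(as.logical(mask), dates, sum))
  data.frame(date = as.Date(names(table(dates))),
             wear_minutes = wear, monitored_minutes = monitored,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply a valid-day criterion
#'
#' A monitored day is valid when its wear time meets the criterion
#' (inclusive: 480 wear minutes satisfy the 8-h criterion).
#'
#' @param days Data frame from [day_wear()].
#' @param criterion_hours Numeric vector of criteria in hours (default
#'   `c(8, 10, 12)`).
#' @param include_partial_days Keep partial first/last days (default `TRUE`;
#'   a partial day can still accumulate 8 h of wear).
#' @return List with `per_day` (the input plus one logical `valid_Xh` column
#'   per criterion), `n_valid` (named integer vector), `any_valid` and
#'   `four_plus` (named logicals: at least 1, at least 4 valid days).
#' @export
valid_days <- function(days, criterion_hours = c(8, 10, 12),
                       include_partial_days = TRUE) {
  if (!include_partial_days) {
    days <- days[days$monitored_minutes == 1440L, , drop = FALSE]
  }
  n_valid <- integer(0)
  for (h in criterion_hours) {
    v <- days$wear_minutes >= h * 60
    days[[sprintf("valid_%gh", h)]] <- v
    n_valid[sprintf("%gh", h)] <- sum(v)
  }
  list(per_day = days, n_valid = n_valid,
       any_valid = n_valid >= 1L, four_plus = n_valid >= 4L)
}

#' Tabulate the valid-day distribution of a cohort
#'
#' For each sex, age bin and wear criterion, the percentage of participants
#' with 0, 1, ..., 7 valid days (counts above 7 are capped at 7, so each row
#' sums to 100%), plus the cumulative `ge1` and `ge4` columns. An overall
#' row per sex and criterion aggregates across age bins.
#'
#' @param cohort Data frame with one baseline row per participant per
#'   criterion: columns `participant_id`, `age` (years), `sex` (`"male"` /
#'   `"female"`), `criterion_hours`, `n_valid`.
#' @param age_bins Numeric vector of bin lower edges plus final upper edge
#'   (default the child/adolescent bins 3--5, 6--8, 9--11, 12--14, 15--18).
#' @return Data frame with columns `sex`, `age_group`, `criterion_hours`,
#'   `n`, `d0` ... `d7`, `ge1`, `ge4`. Empty sex-by-age cells are omitted
#'   (absent, not zero).
#' @export
tabulate_valid_day_distribution <- function(cohort,
                                            age_bins = c(3, 6, 9, 12, 15, 19)) {
  stopifnot(all(c("participant_id", "age", "sex", "criterion_hours",
                  "n_valid") %in% names(cohort)))
  if (anyDuplicated(cohort[, c("participant_id", "criterion_hours")])) {
    stop("each participant must have exactly one baseline record per criterion")
  }
  labels <- paste(head(age_bins, -1L), c(age_bins[-c(1L, length(age_bins))] - 1,
                                         age_bins[length(age_bins)] - 1),
                  sep = " to ")
  cohort$age_group <- cut(cohort$age, breaks = age_bins, labels = labels,
                          right = FALSE, include.lowest = TRUE)
  row_of <- function(sub, sex, grp, crit) {
    capped <- pmin(sub$n_valid, 7L)
    pct <- 100 * tabulate(capped + 1L, nbins = 8L) / nrow(sub)
    out <- data.frame(sex = sex, age_group = grp, criterion_hours = crit,
                      n = nrow(sub), stringsAsFactors = FALSE)
    out[paste0("d", 0:7)] <- as.list(pct)
    out$ge1 <- sum(pct[-1L])
    out$ge4 <- sum(pct[5:8])
    out
  }
  res <- list()
  for (sex in unique(cohort$sex)) {
    for (crit in sort(unique(cohort$criterion_hours))) {
      sel <- cohort$sex == sex & cohort$criterion_hours == crit
      for (grp in labels) {
        sub <- cohort[sel & !is.na(cohort$age_group) & cohort$age_group == grp, ]
        if (nrow(sub) == 0L) next
        res[[length(res) + 1L]] <- row_of(sub, sex, grp, crit)
      }
      sub <- cohort[sel & !is.na(cohort$age_group), ]
      if (nrow(sub) > 0L) {
        res[[length(res) + 1L]] <- row_of(sub, sex, "overall", crit)
      }
    }
  }
  do.call(rbind, res)
}
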