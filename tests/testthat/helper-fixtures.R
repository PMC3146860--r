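# fixtures are built in code; nothing is read from disk

# a minute-resolution series starting at local midnight
minute_series <- function(counts, start = "2005-04-11 00:00:00", ...) {
  epoch_series(counts, start, epoch_length = 60L, ...)
}

# random minute counts: zero-inflated so long zero runs occur naturally
random_minute_counts <- function(n, p_zero = 0.7, max_count = 3000L) {
  nonzero <- stats::runif(n) >= p_zero
  counts <- integer(n)
  counts[nonzero] <- sample.int(max_count, sum(nonzero), replace = TRUE)
  counts
}

# one full 1440-min day with a realistic wear window starting at `wear_from`
# minutes after midnight: category minutes are filled in order with counts
# representative of each category under the default (evenson) cutpoints,
# alternating two values so no count plateau arises by construction
day_counts <- function(sedentary = 0L, light = 0L, moderate = 0L,
                       vigorous = 0L, wear_from = 420L) {
  alt <- function(v1, v2, n) rep_len(c(v1, v2), n)
  x <- c(alt(40L, 60L, sedentary), alt(400L, 600L, light),
         alt(2500L, 3000L, moderate), alt(4500L, 5000L, vigorous))
  stopifnot(wear_from + length(x) <= 1440L)
  c(integer(wear_from), x, integer(1440L - wear_from - length(x)))
}

# minute-of-day computed from public timestamps (independent of the
# package's internal epoch arithmetic)
minute_of_day_pub <- function(series) {
  lt <- as.POSIXlt(epoch_timestamps(series), tz = "UTC")
  lt$hour * 60L + lt$min
}

# independent R-side brute force for the plateau rule: scan all start/length
# pairs for maximal runs
plateau_bruteforce <- function(counts, min_run = 3L, min_value = 10L) {
  hits <- list()
  i <- 1L
  n <- length(counts)
  while (i <= n) {
    j <- i
    while (j < n && counts[j + 1L] == counts[i]) j <- j + 1L
    if (j - i + 1L >= min_run && counts[i] >= min_value) {
      hits[[length(hits) + 1L]] <- data.frame(start_index = i,
                                              length = j - i + 1L,
                                              value = counts[i])
    }
    i <- j + 1L
  }
  if (!length(hits)) {
    data.frame(start_index = integer(), length = integer(), value = integer())
  } else do.call(rbind, hits)
}

# full pipeline on a generated cohort; returns paths of the written outputs
run_pipeline_to_dir <- function(cohort, out_dir, pool_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- list()
  summaries <- list()
  for (id in names(cohort$files)) {
    s <- cohort$files[[id]]
    if (s$epoch_length != 60L) s <- reintegrate(s)
    m <- detect_nonwear(s)
    reports[[id]] <- classify_file(s, m)
    summaries[[id]] <- summarize_day(s, m)
  }
  day_summaries <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  participants <- assign_ids(
    harmonize_phenotypes(stats::setNames(list(cohort$phenotypes),
                                         cohort$phenotypes$study_id[1]),
                         min_studies = 1L)$participants,
    seed = pool_seed)
  db <- build_database(day_summaries, reports, participants)
  write_flag_report(reports, file.path(out_dir, "flags.tsv"))
  utils::write.table(format(db$data), file.path(out_dir, "pooled.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(db$attrition, file.path(out_dir, "attrition.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(db = db, dir = out_dir))
}
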