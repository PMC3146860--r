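#' Dialect configuration for legacy .dat count files
#'
#' Legacy Actigraph count files are plain text: a 10-line header declaring the
#' serial number, start time/date, epoch period and download time/date,
#' followed by integer counts. Real files from multinational studies vary in
#' delimiter and in whether header dates are month-first or day-first, so the
#' reader/writer takes an explicit dialect.
#'
#' @param sep Body token separator: `"whitespace"` or `","`.
#' @param date_format Header date order: `"mdy"` or `"dmy"`.
#' @param header `"canonical"` (exact 10-line layout) or `"permissive"`
#'   (labeled-line search for the four needed fields anywhere in the leading
#'   non-numeric block).
#' @return A list of class `dat_dialect`.
#' @export
dat_dialect <- function(sep = c("whitespace", ","),
                        date_format = c("mdy", "dmy"),
                        header = c("canonical", "permissive")) {
  structure(list(sep = match.arg(sep), date_format = match.arg(date_format),
                 header = match.arg(header)),
            class = "dat_dialect")
}

corrupt_file_error <- function(msg, path = NULL, offset = NULL) {
  detail <- msg
  if (!is.null(offset)) detail <- sprintf("%s (byte offset %d)", detail, offset)
  if (!is.null(path)) detail <- sprintf("%s [%s]", detail, path)
  stop(structure(class = c("accelpool_corrupt_file", "error", "condition"),
                 list(message = detail, call = sys.call(-1))))
}

#' Is a condition a corrupt-file error?
#' @param e A condition object.
#' @return Logical.
#' @export
is_corrupt_file_error <- function(e) inherits(e, "accelpool_corrupt_file")

fmt_header_date <- function(d, date_format) {
  d <- as.POSIXlt(d, tz = "UTC")
  if (date_format == "mdy") {
    sprintf("%02d/%02d/%04d", d$mon + 1L, d$mday, d$year + 1900L)
  } else {
    sprintf("%02d/%02d/%04d", d$mday, d$mon + 1L, d$year + 1900L)
  }
}

parse_header_date <- function(s, date_format) {
  parts <- suppressWarnings(as.integer(strsplit(trimws(s), "[/-]")[[1]]))
  if (length(parts) != 3L || anyNA(parts)) return(NULL)
  if (date_format == "mdy") {
    y <- parts[3]; m <- parts[1]; d <- parts[2]
  } else {
    y <- parts[3]; m <- parts[2]; d <- parts[1]
  }
  if (m < 1L || m > 12L || d < 1L || d > 31L) return(NULL)
  out <- suppressWarnings(as.Date(sprintf("%04d-%02d-%02d", y, m, d)))
  if (is.na(out)) NULL else out
}

parse_epoch_period <- function(s) {
  parts <- suppressWarnings(as.integer(strsplit(trimws(s), ":")[[1]]))
  if (length(parts) != 3L || anyNA(parts)) return(NULL)
  sec <- parts[1] * 3600L + parts[2] * 60L + parts[3]
  if (sec < 1L || sec > 60L || 60L %% sec != 0L) return(NULL)
  sec
}

# byte offset of line i (1-based) within the raw file text
line_offset <- function(lines, i) {
  if (i <= 1L) return(0L)
  sum(nchar(lines[seq_len(i - 1L)], type = "bytes") + 1L)
}

#' Read a legacy Actigraph count file
#'
#' Parses the plain-text header (serial number, start time/date, epoch
#' period) and the integer count body. Parsing is loss-free: writing the
#' returned series back with [write_count_file()] reproduces the input, and
#' the number of counts always equals the number of integer tokens in the
#' body (no silent truncation).
#'
#' @param path File path.
#' @param dialect A [dat_dialect()].
#' @param study_id,participant_id,wave Optional bookkeeping attached to the
#'   returned series (legacy headers carry no study metadata).
#' @return An [epoch_series()].
#' @section Errors: An unparseable header, an empty body, or a negative or
#'   non-integer body token raises a corrupt-file error (class
#'   `accelpool_corrupt_file`) carrying the byte offset of the offending
#'   line. Counts above the 32767 saturation ceiling are read with a warning;
#'   classifying such files is the cleaning module's responsibility.
#' @export
read_count_file <- function(path, dialect = dat_dialect(),
                            study_id = "", participant_id = "", wave = "1") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  is_body <- function(x) {
    grepl("^[-0-9.,[:space:]]*$", x) & grepl("[0-9]", x)
  }
  # header = leading block of non-numeric lines
  body_start <- which(is_body(lines) & nzchar(trimws(lines)))
  body_start <- if (length(body_start)) body_start[1] else length(lines) + 1L
  hdr <- lines[seq_len(body_start - 1L)]

  grab <- function(pattern, line_no = NULL) {
    if (!is.null(line_no) && dialect$header == "canonical") {
      if (line_no > length(hdr)) return(NULL)
      cand <- hdr[line_no]
      if (!grepl(pattern, cand, ignore.case = TRUE)) return(NULL)
    } else {
      hit <- grep(pattern, hdr, ignore.case = TRUE, value = TRUE)
      if (!length(hit)) return(NULL)
      cand <- hit[1]
    }
    trimws(sub(paste0(".*", pattern, "[[:space:]:]*"), "", cand,
               ignore.case = TRUE))
  }
  serial <- grab("Serial Number", 2L)
  start_time <- grab("Start Time", 3L)
  start_date <- grab("Start Date", 4L)
  epoch_str <- grab("Epoch Period \\(hh:mm:ss\\)", 5L)
  dl_time <- grab("Download Time", 6L)
  dl_date <- grab("Download Date", 7L)
  for (fld in list(c("Serial Number", serial), c("Start Time", start_time),
                   c("Start Date", start_date), c("Epoch Period", epoch_str))) {
    if (is.null(fld[[2]]) || !nzchar(fld[[2]])) {
      corrupt_file_error(paste0("header field not found: ", fld[[1]]),
                         path, 0L)
    }
  }
  epoch <- parse_epoch_period(epoch_str)
  if (is.null(epoch)) {
    corrupt_file_error(paste0("unparseable epoch period: ", epoch_str), path,
                       line_offset(lines, 5L))
  }
  sdate <- parse_header_date(start_date, dialect$date_format)
  if (is.null(sdate) || !grepl("^\\d{1,2}:\\d{2}:\\d{2}$", trimws(start_time))) {
    corrupt_file_error("unparseable start date/time", path,
                       line_offset(lines, 3L))
  }
  start_dt <- as.POSIXct(paste(format(sdate), trimws(start_time)), tz = "UTC")

  body <- lines[seq.int(body_start, length.out = max(0L, length(lines) - body_start + 1L))]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) corrupt_file_error("empty count body", path,
                                        line_offset(lines, body_start))
  split_re <- if (dialect$sep == ",") "[,[:space:]]+" else "[[:space:]]+"
  tokens <- unlist(strsplit(trimws(body), split_re), use.names = FALSE)
  tokens <- tokens[nzchar(tokens)]
  bad <- !grepl("^-?[0-9]+$", tokens)
  if (any(bad)) {
    corrupt_file_error(paste0("non-integer count token: ", tokens[bad][1]),
                       path, line_offset(lines, body_start))
  }
  counts <- as.numeric(tokens)
  if (any(counts < 0)) {
    corrupt_file_error(paste0("negative count: ", min(counts)), path,
                       line_offset(lines, body_start))
  }
  if (any(counts > 32767)) {
    warning("counts exceed the 32767 device saturation ceiling in ", path,
            "; file is a flag candidate")
  }
  stem <- sub("\\.[^.]*$", "", basename(path))
  series <- suppressWarnings(epoch_series(
    counts, start_dt, epoch_length = epoch, serial_number = serial,
    device_model = guess_model(serial), study_id = study_id,
    participant_id = participant_id, wave = wave, file_label = stem))
  series$download_datetime <-
    if (!is.null(dl_date) && !is.null(dl_time) && nzchar(dl_date) && nzchar(dl_time)) {
      d <- parse_header_date(dl_date, dialect$date_format)
      if (is.null(d)) NULL else as.POSIXct(paste(format(d), trimws(dl_time)), tz = "UTC")
    } else NULL
  series
}

guess_model <- function(serial) {
  if (grepl("^CSA|^MTI|^716[04]", serial)) "7164"
  else if (grepl("^71256", serial)) "71256"
  else if (grepl("^LYN|^GT1M|^MAT", serial)) "GT1M"
  else "unknown"
}

#' Write a legacy Actigraph count file
#'
#' Emits the canonical 10-line header followed by the counts, 10 per line.
#' Round-trip identity holds: `read_count_file(write_count_file(s))`
#' reproduces the counts, epoch length, start datetime and serial number of
#' `s` exactly.
#'
#' @param series An [epoch_series()].
#' @param path Output path.
#' @param dialect A [dat_dialect()].
#' @return `path`, invisibly.
#' @export
write_count_file <- function(series, path, dialect = dat_dialect()) {
  stopifnot(inherits(series, "epoch_series"))
  ep <- series$epoch_length
  dl <- series$download_datetime
  if (is.null(dl)) dl <- series$start_datetime + length(series$counts) * ep
  hdr <- c(
    "--- Data Table File ---",
    paste0("Serial Number: ", series$serial_number),
    paste0("Start Time ", format(series$start_datetime, "%H:%M:%S")),
    paste0("Start Date ", fmt_header_date(series$start_datetime, dialect$date_format)),
    sprintf("Epoch Period (hh:mm:ss) %02d:%02d:%02d",
            ep %/% 3600L, (ep %% 3600L) %/% 60L, ep %% 60L),
    paste0("Download Time ", format(dl, "%H:%M:%S")),
    paste0("Download Date ", fmt_header_date(dl, dialect$date_format)),
    "Current Memory Address: 0",
    "Current Battery Voltage: 4.12     Mode = 0",
    "--------------------------------------------------")
  cnt <- series$counts
  pad <- (10L - length(cnt) %% 10L) %% 10L
  rows <- matrix(c(as.character(cnt), rep("", pad)), ncol = 10L, byrow = TRUE)
  collapse <- if (dialect$sep == ",") "," else "  "
  body <- apply(rows, 1L, function(r) paste(r[nzchar(r)], collapse = collapse))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Reconstitute a headerless time-stamped count table
#'
#' Public exports of some surveys (NHANES-style) provide per-minute counts
#' without the device header. This rebuilds a standard count series with a
#' start time of 00:00:00 and 60-s epochs. Because the true start date is
#' withheld, the start date is set to the unique date in January 1--7 of
#' `cycle_year` whose weekday matches `day_of_week`, preserving the day of
#' the week of the original recording.
#'
#' @param table Data frame with columns `time` (`"HH:MM:SS"` strings or
#'   minute-of-day integers, consecutive from midnight, wrapping daily) and
#'   `count` (integers). An optional first column of day indices or dates is
#'   ignored beyond ordering.
#' @param cycle_year Integer year recorded for the survey cycle (e.g. 2004
#'   for a 2003--04 cycle, 2006 for 2005--06).
#' @param day_of_week Weekday of the first monitored day, 1 = Sunday ...
#'   7 = Saturday (survey-file convention).
#' @param ... Passed to [epoch_series()] (ids, serial).
#' @return An [epoch_series()] starting at 00:00:00 with 60-s epochs.
#' @section Errors: Gaps in the minute grid raise a corrupt-file error;
#'   `day_of_week` outside 1..7 is an error.
#' @export
reconstitute_headerless <- function(table, cycle_year, day_of_week, ...) {
  stopifnot(is.data.frame(table))
  if (!is.numeric(day_of_week) || length(day_of_week) != 1L ||
      day_of_week < 1 || day_of_week > 7) {
    stop("day_of_week must be in 1..7 (1 = Sunday)")
  }
  tcol <- if ("time" %in% names(table)) table$time else table[[ncol(table) - 1L]]
  counts <- if ("count" %in% names(table)) table$count else table[[ncol(table)]]
  mins <- if (is.numeric(tcol)) as.integer(tcol) else {
    p <- strsplit(as.character(tcol), ":")
    vapply(p, function(x) as.integer(x[1]) * 60L + as.integer(x[2]), 0L)
  }
  expected <- (seq_along(mins) - 1L) %% 1440L
  if (mins[1] != 0L) corrupt_file_error("table must begin at 00:00:00")
  gap <- which(mins != expected)
  if (length(gap)) {
    corrupt_file_error(sprintf("gap in minute grid at row %d (expected %02d:%02d)",
                               gap[1], expected[gap[1]] %/% 60L,
                               expected[gap[1]] %% 60L))
  }
  # candidate start dates: Jan 1-7 of the cycle year; weekdays there cover 1..7 once
  cand <- as.Date(sprintf("%04d-01-%02d", cycle_year, 1:7))
  wd <- as.POSIXlt(cand)$wday + 1L    # POSIXlt wday: 0 = Sunday
  start_date <- cand[wd == day_of_week]
  stopifnot(length(start_date) == 1L)
  epoch_series(counts, as.POSIXct(paste(format(start_date), "00:00:00"),
                                  tz = "UTC"),
               epoch_length = 60L, ...)
}

#' Read a start-date/time exception list
#'
#' Delimited text with columns `file_key`, `start_date` (ISO, may be blank)
#' and `start_time` (`HH:MM:SS`, may be blank); at least one of date/time
#' must be present per row, and keys must be unique.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return Data frame of exceptions.
#' @export
read_start_exceptions <- function(path, sep = "\t") {
  ex <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  validate_start_exceptions(ex)
}

validate_start_exceptions <- function(ex) {
  stopifnot(all(c("file_key", "start_date", "start_time") %in% names(ex)))
  ex$start_date[is.na(ex$start_date)] <- ""
  ex$start_time[is.na(ex$start_time)] <- ""
  if (anyDuplicated(ex$file_key)) {
    stop("duplicate keys in exception list: ",
         paste(unique(ex$file_key[duplicated(ex$file_key)]), collapse = ", "))
  }
  empty <- !nzchar(trimws(ex$start_date)) & !nzchar(trimws(ex$start_time))
  if (any(empty)) {
    stop("exception rows must set a start date and/or time: row ",
         which(empty)[1])
  }
  ex
}

#' Apply start-date/time exceptions to a series
#'
#' Monitors initialized before deployment carry a wrong start stamp; a
#' read-in exception list corrects the start date and/or time for the keyed
#' files. Counts are never touched, and non-matching series are returned
#' unchanged. Every applied correction is recorded in the series' provenance
#' (see [provenance()]).
#'
#' @param series An [epoch_series()].
#' @param exceptions Data frame as returned by [read_start_exceptions()].
#' @return The (possibly corrected) [epoch_series()].
#' @export
apply_start_exceptions <- function(series, exceptions) {
  exceptions <- validate_start_exceptions(exceptions)
  hit <- exceptions[exceptions$file_key == file_key(series), , drop = FALSE]
  if (nrow(hit) == 0L) return(series)
  old <- series$start_datetime
  new_date <- if (nzchar(trimws(hit$start_date))) trimws(hit$start_date) else
    format(old, "%Y-%m-%d")
  new_time <- if (nzchar(trimws(hit$start_time))) trimws(hit$start_time) else
    format(old, "%H:%M:%S")
  series$start_datetime <- as.POSIXct(paste(new_date, new_time), tz = "UTC")
  add_provenance(series, "start_corrected", 1L, length(series$counts),
                 sprintf("start %s -> %s", format(old, "%Y-%m-%d %H:%M:%S"),
                         format(series$start_datetime, "%Y-%m-%d %H:%M:%S")))
}

#' Processing provenance of a series
#'
#' Actions that alter a series (start corrections, dropped reintegration
#' tails, DST imputation/collapse) are logged on the object itself so a
#' pooled database row can always be traced back.
#'
#' @param series An [epoch_series()].
#' @return Data frame with columns `action`, `start_epoch`, `end_epoch`,
#'   `detail` (zero rows if untouched).
#' @export
provenance <- function(series) {
  p <- series$provenance
  if (is.null(p)) {
    p <- data.frame(action = character(), start_epoch = integer(),
                    end_epoch = integer(), detail = character(),
                    stringsAsFactors = FALSE)
  }
  p
}

add_provenance <- function(series, action, start_epoch, end_epoch, detail) {
  series$provenance <- rbind(
    provenance(series),
    data.frame(action = action, start_epoch = as.integer(start_epoch),
               end_epoch = as.integer(end_epoch), detail = detail,
               stringsAsFactors = FALSE))
  series
}
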