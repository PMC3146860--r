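#' Simulation configuration for synthetic cohorts
#'
#' Describes a cohort of children/adolescents wearing a waist-mounted
#' uniaxial count accelerometer during waking hours: diurnal wear with
#' overnight removal, occasional daytime removal episodes, activity arriving
#' as a sedentary/light background punctuated by short MVPA bursts with
#' geometric-like lengths, and optional injection of the three device
#' artifact types (whole-hour temporal shift, saturation plateau at 32767,
#' non-return-to-baseline night floor).
#'
#' Counts are drawn uniformly within the active cutpoint set's interval for
#' each minute's true category, so intensity classification can recover the
#' generated truth exactly. Three structural guarantees keep the generated
#' truth identifiable by the pipeline's own rules: every 15-minute wear
#' block contains a nonzero minute (so wear is never absorbed into a
#' non-wear window), the first and last three minutes of each wear segment
#' are nonzero (so non-wear windows cannot creep across a boundary), and no
#' three consecutive equal counts at or above 10 survive generation (so the
#' plateau rule fires only on injected plateaus).
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed (mandatory; the whole module is deterministic
#'   given it).
#' @param study_id Study label stamped on files and phenotypes.
#' @param deployment_days Monitored days per file, 2--7.
#' @param epoch_length Recording epoch in seconds (60, or a divisor of 60;
#'   sub-minute files carry the same minute-level truth and are meant to be
#'   reintegrated).
#' @param age_range Uniform age range in years.
#' @param wake_start,wake_end Wear period, minutes of day (default
#'   07:00--22:00).
#' @param removal_prob Probability of one daytime removal episode per day.
#' @param removal_length Range of removal episode lengths, minutes (kept
#'   below the temporal-shift day-block criterion so removals never mimic a
#'   shifted file).
#' @param nonwear_spike_prob Probability that an overnight non-wear episode
#'   contains 1--2 isolated nonzero spike minutes (the interruptions the
#'   wear rule tolerates).
#' @param p_sedentary Probability a background wear minute is sedentary
#'   (else light).
#' @param p_zero_given_sedentary Probability a sedentary minute registers
#'   exactly zero counts.
#' @param burst_rate Per-minute probability of starting an MVPA burst.
#' @param burst_mean_length Mean burst length, minutes (geometric).
#' @param p_vigorous_in_burst Probability a burst minute is vigorous rather
#'   than moderate.
#' @param overnight_wear_prob Probability a participant legitimately wears
#'   the device overnight (sleep wear; default 0).
#' @param artifact_rates Named numeric: probability a file receives each
#'   artifact (`temporal_shift`, `saturation_plateau`,
#'   `no_baseline_return`); at most one artifact per file.
#' @param cutpoints [cutpoint_set()] used to translate true categories into
#'   counts (default the first registry entry).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_participants = 20L, seed,
                       study_id = "SYNTH",
                       deployment_days = 7L, epoch_length = 60L,
                       age_range = c(6, 18),
                       wake_start = 420L, wake_end = 1320L,
                       removal_prob = 0.3,
                       removal_length = c(60L, 150L),
                       nonwear_spike_prob = 0.2,
                       p_sedentary = 0.55, p_zero_given_sedentary = 0.5,
                       burst_rate = 0.02, burst_mean_length = 3,
                       p_vigorous_in_burst = 0.3,
                       overnight_wear_prob = 0,
                       artifact_rates = c(temporal_shift = 0,
                                          saturation_plateau = 0,
                                          no_baseline_return = 0),
                       cutpoints = cutpoint_registry()[[1]]) {
  if (missing(seed)) stop("sim_config() requires an explicit seed")
  stopifnot(deployment_days >= 1L, 60L %% epoch_length == 0L,
            wake_end > wake_start, wake_end - wake_start < 1440L,
            all(artifact_rates >= 0), sum(artifact_rates) <= 1,
            removal_prob >= 0, removal_prob <= 1)
  if (wake_end - wake_start >= 1440L) stop("infeasible wear schedule")
  structure(as.list(environment()), class = "sim_config")
}

# draw a count for one minute of the given true category, uniform within
# the category's cutpoint interval
draw_count <- function(category, cfg) {
  b <- cfg$cutpoints$boundaries
  switch(category,
         sedentary = if (stats::runif(1) < cfg$p_zero_given_sedentary) 0L else
           sample.int(b[2] - 1L, 1L),
         light = sample.int(b[3] - b[2], 1L) + b[2] - 1L,
         moderate = sample.int(b[4] - b[3], 1L) + b[3] - 1L,
         vigorous = sample.int(3000L, 1L) + b[4] - 1L)
}

# generate one participant-file at minute resolution; returns counts,
# truth labels (chr), truth wear (logical)
generate_minutes <- function(cfg) {
  n <- cfg$deployment_days * 1440L
  mod <- (seq_len(n) - 1L) %% 1440L
  day <- (seq_len(n) - 1L) %/% 1440L + 1L
  overnight_wearer <- stats::runif(1) < cfg$overnight_wear_prob
  wear <- if (overnight_wearer) rep(TRUE, n) else
    mod >= cfg$wake_start & mod < cfg$wake_end
  # daytime removal episodes
  for (d in seq_len(cfg$deployment_days)) {
    if (stats::runif(1) < cfg$removal_prob) {
      len <- sample.int(cfg$removal_length[2] - cfg$removal_length[1] + 1L, 1L) +
        cfg$removal_length[1] - 1L
      start_mod <- sample.int(1020L - 540L - len, 1L) + 540L  # within 09:00-17:00
      idx <- (d - 1L) * 1440L + start_mod + seq_len(len)
      wear[idx] <- FALSE
    }
  }
  labels <- rep("nonwear", n)
  counts <- integer(n)
  # background + bursts over wear minutes
  widx <- which(wear)
  in_burst <- 0L
  for (i in widx) {
    if (in_burst > 0L) {
      labels[i] <- if (stats::runif(1) < cfg$p_vigorous_in_burst) "vigorous" else "moderate"
      in_burst <- in_burst - 1L
    } else if (stats::runif(1) < cfg$burst_rate) {
      in_burst <- stats::rgeom(1, 1 / cfg$burst_mean_length)
      labels[i] <- if (stats::runif(1) < cfg$p_vigorous_in_burst) "vigorous" else "moderate"
    } else {
      labels[i] <- if (stats::runif(1) < cfg$p_sedentary) "sedentary" else "light"
    }
    counts[i] <- draw_count(labels[i], cfg)
  }
  # identifiability guarantee 1: every 15-min wear block has a nonzero minute
  seg <- rle(wear)
  seg_end <- cumsum(seg$lengths)
  seg_start <- seg_end - seg$lengths + 1L
  b2 <- cfg$cutpoints$boundaries[2]
  small_nonzero <- function() sample.int(b2 - 1L, 1L)
  for (s in which(seg$values)) {
    lo <- seg_start[s]; hi <- seg_end[s]
    # guarantee 2: nonzero edges (3 min each side, or all if shorter)
    edge <- unique(c(lo:min(lo + 2L, hi), max(hi - 2L, lo):hi))
    for (i in edge[counts[edge] == 0L]) counts[i] <- small_nonzero()
    blocks <- split(lo:hi, (lo:hi - lo) %/% 15L)
    for (blk in blocks) {
      if (all(counts[blk] == 0L)) {
        pick <- blk[sample.int(length(blk), 1L)]
        counts[pick] <- small_nonzero()
      }
    }
  }
  # overnight spike interruptions (nonwear per the wear rule's tolerance)
  if (!overnight_wearer) {
    for (s in which(!seg$values)) {
      lo <- seg_start[s]; hi <- seg_end[s]
      if (hi - lo + 1L >= 60L && stats::runif(1) < cfg$nonwear_spike_prob) {
        k <- sample.int(2L, 1L)
        pos <- sample((lo + 2L):(hi - 2L), k)
        counts[pos] <- sample(200:800, k, replace = TRUE)
      }
    }
  }
  # guarantee 3: break accidental plateaus (3 identical consecutive >= 10)
  for (i in seq_len(n)[-(1:2)]) {
    if (counts[i] >= 10L && counts[i] == counts[i - 1L] &&
        counts[i] == counts[i - 2L]) {
      counts[i] <- counts[i] + if (category_upper_ok(counts[i], labels[i], cfg)) 1L else -1L
    }
  }
  list(counts = counts, labels = labels, wear = wear,
       overnight_wearer = overnight_wearer)
}

# can we add 1 to this count without leaving its category interval?
category_upper_ok <- function(count, label, cfg) {
  b <- cfg$cutpoints$boundaries
  upper <- switch(label, sedentary = b[2] - 1L, light = b[3] - 1L,
                  moderate = b[4] - 1L, vigorous = .Machine$integer.max,
                  nonwear = 32766L)
  count + 1L <= upper
}

#' Artifact presets guaranteed detectable
#'
#' Parameter presets per artifact kind that exceed the cleaning module's
#' detection thresholds by construction, so recovery tests are well-posed.
#'
#' @param kind One of `"temporal_shift"`, `"saturation_plateau"`,
#'   `"no_baseline_return"`.
#' @return Named list of parameters.
#' @export
artifact_presets <- function(kind = c("temporal_shift", "saturation_plateau",
                                      "no_baseline_return")) {
  switch(match.arg(kind),
         temporal_shift = list(shift_hours = 6L),
         saturation_plateau = list(run_length = 30L, value = 32767L),
         no_baseline_return = list(floor = 30L, jitter = 5L,
                                   night_hours = 0:5))
}

#' Inject a device artifact into a series
#'
#' * `temporal_shift` rotates the whole series forward by
#'   `params$shift_hours` whole hours (circularly), so activity appears at
#'   night and zero runs in the day on every monitored day.
#' * `saturation_plateau` overwrites a daytime run of `params$run_length`
#'   epochs (>= 3) with the 32767 saturation value.
#' * `no_baseline_return` replaces zero counts in the night hours with a
#'   constant floor plus a small jitter (`floor + 0..jitter`), the signature
#'   of a sensor that no longer returns to baseline.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param kind Artifact kind.
#' @param params Parameters (default the detectable [artifact_presets()]).
#' @param start_index For `saturation_plateau`: first epoch of the run
#'   (default: late morning of day 1).
#' @return List with `series` (modified) and `label` (kind + parameters +
#'   `sub_threshold` marker when params fall below the documented
#'   detectable regime).
#' @export
inject_artifact <- function(series, kind, params = artifact_presets(kind),
                            start_index = NULL) {
  require_minute_epochs(series, "inject_artifact()")
  n <- length(series$counts)
  sub_threshold <- FALSE
  if (kind == "temporal_shift") {
    s <- params$shift_hours * 60L
    series$counts <- series$counts[((seq_len(n) - 1L - s) %% n) + 1L]
    label <- list(kind = kind, shift_hours = params$shift_hours)
  } else if (kind == "saturation_plateau") {
    if (params$run_length < 3L) sub_threshold <- TRUE
    if (is.null(start_index)) {
      start_index <- 600L  # 10:00 of day 1
    }
    idx <- start_index:(start_index + params$run_length - 1L)
    idx <- idx[idx <= n]
    old <- series$counts
    series <- suppressWarnings(within_series_counts(series, replace(old, idx, params$value)))
    label <- list(kind = kind, run_length = params$run_length,
                  value = params$value, start_index = start_index)
  } else if (kind == "no_baseline_return") {
    mod <- minute_of_day(series)
    night <- (mod %/% 60L) %in% params$night_hours
    zeroes <- night & series$counts == 0L
    jit <- if (is.null(params$jitter)) 0L else params$jitter
    series$counts[zeroes] <- params$floor +
      sample.int(jit + 1L, sum(zeroes), replace = TRUE) - 1L
    if (params$floor < 1L) sub_threshold <- TRUE
    label <- list(kind = kind, floor = params$floor)
  } else stop("unknown artifact kind: ", kind)
  label$sub_threshold <- sub_threshold
  list(series = series, label = label)
}

# swap the counts of a series, preserving everything else (keeps the
# constructor's invariant checks out of artifact injection, which is allowed
# to produce saturation values)
within_series_counts <- function(series, counts) {
  series$counts <- as.integer(counts)
  series
}

# expand minute counts to sub-minute epochs such that reintegration
# recovers the minute series exactly (even split, remainder spread first)
expand_to_subepochs <- function(counts, epoch_length) {
  k <- 60L %/% epoch_length
  if (k == 1L) return(counts)
  base <- counts %/% k
  rem <- counts %% k
  out <- matrix(rep(base, each = k), nrow = k)
  add <- sapply(rem, function(r) c(rep(1L, r), rep(0L, k - r)))
  as.integer(out + add)
}

#' Generate a synthetic accelerometer cohort
#'
#' Produces one count file per participant together with full ground truth
#' (true wear mask, true per-minute intensity labels, true per-day intensity
#' minutes, injected artifact labels) and a phenotype table. Deterministic
#' given `config$seed`: two runs with the same configuration are identical.
#'
#' @param config A [sim_config()].
#' @return List with `files` (list of [epoch_series()]), `truth` (list per
#'   file: `wear` [wear_mask()], `labels`, `day_minutes`, `artifact`),
#'   `phenotypes` (data frame with `study_id`, `participant_id`, `wave`,
#'   `age`, `sex`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  phen <- data.frame(
    study_id = config$study_id,
    participant_id = sprintf("%s%04d", config$study_id, seq_len(n)),
    wave = 1L,
    age = round(stats::runif(n, config$age_range[1], config$age_range[2]), 1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  kinds <- names(config$artifact_rates)
  artifact_of <- apply(stats::rmultinom(n, 1L,
                                        c(config$artifact_rates,
                                          none = 1 - sum(config$artifact_rates))),
                       2L, function(col) c(kinds, "none")[which(col == 1L)])
  start_date <- as.POSIXct("2005-04-11 00:00:00", tz = "UTC")
  files <- vector("list", n)
  truth <- vector("list", n)
  for (p in seq_len(n)) {
    g <- generate_minutes(config)
    series <- epoch_series(
      expand_to_subepochs(g$counts, config$epoch_length),
      start_date, epoch_length = config$epoch_length,
      serial_number = sprintf("MAT2%05d", p), device_model = "GT1M",
      study_id = config$study_id, participant_id = phen$participant_id[p],
      wave = "1", file_label = sprintf("%s_%04d_w1", config$study_id, p))
    art <- NULL
    if (artifact_of[p] != "none") {
      if (config$epoch_length != 60L) {
        stop("artifact injection is defined on 60-s files; use epoch_length = 60")
      }
      inj <- inject_artifact(series, artifact_of[p])
      series <- inj$series
      art <- inj$label
      if (artifact_of[p] == "temporal_shift") {
        s <- art$shift_hours * 60L
        nmin <- length(g$counts)
        rot <- function(x) x[((seq_len(nmin) - 1L - s) %% nmin) + 1L]
        g$wear <- rot(g$wear)
        g$labels <- rot(g$labels)
      }
    }
    dates <- as.Date(start_date) + ((seq_along(g$counts) - 1L) %/% 1440L)
    dm <- data.frame(date = sort(unique(dates)))
    for (cat in c("sedentary", "light", "moderate", "vigorous")) {
      dm[[cat]] <- as.integer(tapply(g$labels == cat, dates, sum))
    }
    dm$wear_minutes <- as.integer(tapply(g$wear, dates, sum))
    files[[p]] <- series
    truth[[p]] <- list(wear = wear_mask(g$wear), labels = g$labels,
                       day_minutes = dm, artifact = art,
                       overnight_wearer = g$overnight_wearer)
  }
  names(files) <- names(truth) <- phen$participant_id
  list(files = files, truth = truth, phenotypes = phen)
}

#' Write a generated cohort to disk
#'
#' Emits one legacy count file per participant plus `phenotypes.tsv` and a
#' `truth_artifacts.tsv` sidecar (file label, artifact kind, parameters).
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param dialect A [dat_dialect()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = dat_dialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in cohort$files) {
    write_count_file(f, file.path(dir, paste0(f$file_label, ".dat")), dialect)
  }
  utils::write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  art <- do.call(rbind, lapply(names(cohort$truth), function(id) {
    a <- cohort$truth[[id]]$artifact
    data.frame(participant_id = id,
               kind = if (is.null(a)) "none" else a$kind,
               params = if (is.null(a)) "" else
                 paste(names(a)[-1], unlist(a[-1]), sep = "=", collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(art, file.path(dir, "truth_artifacts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
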