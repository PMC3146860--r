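#' Define a per-variable recode map
#'
#' Harmonizes one phenotype variable across studies: per-study mappings from
#' source categories to pooled categories, and/or a per-study unit
#' conversion. Mappings must be total over the declared source categories;
#' an unmapped response is logged and set missing, never silently coerced.
#'
#' @param variable Variable name in the pooled database.
#' @param recode Named list: study id -> named character vector
#'   (source category -> pooled category). Optional.
#' @param convert Named list: study id -> unit-conversion function id, one
#'   of `"identity"`, `"m_to_cm"`, `"cm_to_m"`, `"kg_to_g"`, `"g_to_kg"`,
#'   `"lb_to_kg"`, `"in_to_cm"`. Optional.
#' @return Object of class `recode_map`.
#' @export
recode_map <- function(variable, recode = list(), convert = list()) {
  structure(list(variable = variable, recode = recode, convert = convert),
            class = "recode_map")
}

unit_conversions <- list(
  identity = function(x) x,
  m_to_cm = function(x) x * 100,
  cm_to_m = function(x) x / 100,
  kg_to_g = function(x) x * 1000,
  g_to_kg = function(x) x / 1000,
  lb_to_kg = function(x) x * 0.45359237,
  in_to_cm = function(x) x * 2.54)

#' Harmonize phenotype tables across studies
#'
#' Pools per-study phenotype tables into one participant table. A variable
#' is retained only when declared by at least `min_studies` contributing
#' studies (membership is judged on declared columns, not on non-missing
#' counts). Categorical responses pass through their [recode_map()]; unit
#' conversions are applied per study. Rows lacking age or sex are excluded
#' and returned as `MISSING_PHENOTYPE` flag reports: a file cannot enter the
#' pooled database without them.
#'
#' @param study_tables Named list (study id -> data frame). Each table needs
#'   `participant_id`, `age`, `sex`; a `wave` column defaults to 1.
#' @param recode_maps List of [recode_map()] objects.
#' @param min_studies Minimum studies a variable must appear in (default 3).
#' @return List with `participants` (pooled data frame), `excluded` (list of
#'   [flag_report()]), `dropped_variables` (character), `recode_errors`
#'   (data frame log).
#' @export
harmonize_phenotypes <- function(study_tables, recode_maps = list(),
                                 min_studies = 3L) {
  stopifnot(is.list(study_tables), length(names(study_tables)) == length(study_tables))
  core <- c("participant_id", "age", "sex", "wave")
  maps <- stats::setNames(recode_maps,
                          vapply(recode_maps, function(m) m$variable, ""))
  # variable coverage across studies (excluding core columns)
  extra_vars <- lapply(study_tables, function(tb) setdiff(names(tb), core))
  coverage <- table(unlist(extra_vars))
  keep_vars <- names(coverage)[coverage >= min_studies]
  dropped <- setdiff(names(coverage), keep_vars)

  excluded <- list()
  errors <- data.frame(study_id = character(), participant_id = character(),
                       variable = character(), value = character(),
                       stringsAsFactors = FALSE)
  rows <- list()
  for (sid in names(study_tables)) {
    tb <- study_tables[[sid]]
    stopifnot(all(c("participant_id", "age", "sex") %in% names(tb)))
    if (!"wave" %in% names(tb)) tb$wave <- 1L
    bad <- is.na(tb$age) | is.na(tb$sex) | !nzchar(as.character(tb$sex))
    for (i in which(bad)) {
      key <- paste(sid, tb$participant_id[i], tb$wave[i], sep = "|")
      excluded[[length(excluded) + 1L]] <- flag_report(
        key, "MISSING_PHENOTYPE",
        new_evidence("missing_phenotype", NA_integer_, NA_integer_,
                     paste("missing:", paste(c("age", "sex")[c(is.na(tb$age[i]),
                                                               is.na(tb$sex[i]) || !nzchar(as.character(tb$sex[i])))],
                                             collapse = ","))))
    }
    tb <- tb[!bad, , drop = FALSE]
    out <- tb[, intersect(c(core, keep_vars), names(tb)), drop = FALSE]
    for (v in intersect(keep_vars, names(out))) {
      m <- maps[[v]]
      if (is.null(m)) next
      if (!is.null(m$convert[[sid]])) {
        out[[v]] <- unit_conversions[[m$convert[[sid]]]](out[[v]])
      }
      if (!is.null(m$recode[[sid]])) {
        src <- as.character(out[[v]])
        mapped <- unname(m$recode[[sid]][src])
        unmapped <- !is.na(src) & nzchar(src) & is.na(mapped)
        if (any(unmapped)) {
          errors <- rbind(errors, data.frame(
            study_id = sid, participant_id = out$participant_id[unmapped],
            variable = v, value = src[unmapped], stringsAsFactors = FALSE))
        }
        out[[v]] <- mapped
      }
    }
    for (v in setdiff(keep_vars, names(out))) out[[v]] <- rep(NA, nrow(out))
    out$study_id <- rep(sid, nrow(out))
    rows[[sid]] <- out[, c("study_id", core, keep_vars), drop = FALSE]
  }
  participants <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  participants$sex <- tolower(as.character(participants$sex))
  list(participants = participants, excluded = excluded,
       dropped_variables = dropped, recode_errors = errors)
}

# keyed hash built from two independent 31-bit multiplicative passes.
# Pure-R, deterministic across platforms; used only for id assignment.
keyed_hash <- function(s, salt) {
  bytes <- as.integer(charToRaw(paste0(salt, "|", s)))
  h1 <- 2166136261; h2 <- 40389
  for (b in bytes) {
    h1 <- ((bitwXor(as.integer(h1 %% 2^31), b) %% 2^31) * 16777619) %% 2^31
    h2 <- ((h2 * 31 + b) %% 2^31)
  }
  sprintf("%08x%08x", as.integer(h1 %% 2^31), as.integer(h2))
}

#' Assign anonymized participant ids
#'
#' Maps each `(study_id, participant_id)` pair to an opaque id via a salted
#' keyed hash: deterministic given the seed, bijective on the input keys
#' (collisions are checked and resolved by re-salting), and carrying no
#' substring of the source identifiers. The same participant across waves
#' receives the same id because the wave is not part of the hashed key.
#'
#' @param records Data frame with `study_id` and `participant_id` columns.
#' @param seed Integer salt seed.
#' @return `records` with a `pooled_id` column prepended.
#' @export
assign_ids <- function(records, seed = 1L) {
  key <- paste(records$study_id, records$participant_id, sep = "|")
  ukey <- unique(key)
  salt <- as.character(seed)
  repeat {
    ids <- vapply(ukey, keyed_hash, "", salt = salt, USE.NAMES = TRUE)
    if (!anyDuplicated(ids)) break
    salt <- paste0(salt, "+")  # re-salt on (astronomically unlikely) collision
    message("id collision; regenerating with extended salt")
  }
  leak <- mapply(function(k, id) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    any(nzchar(parts) & nchar(parts) >= 3 & vapply(parts, grepl, TRUE, x = id, fixed = TRUE))
  }, ukey, ids)
  if (any(leak)) {
    salt <- paste0(salt, "#")
    ids <- vapply(ukey, keyed_hash, "", salt = salt, USE.NAMES = TRUE)
  }
  cbind(data.frame(pooled_id = paste0("P", unname(ids[key])),
                   stringsAsFactors = FALSE), records)
}

#' Build the pooled long-format database
#'
#' Joins per-day summaries to flag reports and harmonized participants into
#' one row per file-day. Rows from files flagged `SPURIOUS` or
#' `TEMPORALLY_SHIFTED` are retained but carry `excluded_by_default = TRUE`
#' (exclusion from analysis is recommended, not forced). The attrition
#' report reconciles every file presented to the pipeline:
#' `viable + duplicate + missing-phenotype + no-wear + corrupt + spurious/shifted
#' = total`.
#'
#' @param day_summaries Data frame: rbind of [summarize_day()] outputs.
#' @param flag_reports List of [flag_report()] covering every file key in
#'   `day_summaries` plus any dropped upstream.
#' @param participants Harmonized participant table
#'   (from [harmonize_phenotypes()], after [assign_ids()]).
#' @return List of class `pooled_database`: `data` (long table), `attrition`
#'   (data frame of flag counts), `baseline` (function returning the
#'   earliest-wave row set per pooled id).
#' @export
build_database <- function(day_summaries, flag_reports, participants) {
  stopifnot(is.data.frame(day_summaries), "pooled_id" %in% names(participants))
  flags <- data.frame(
    file_key = vapply(flag_reports, function(r) r$file_key, ""),
    flag = vapply(flag_reports, function(r) r$flag, ""),
    stringsAsFactors = FALSE)
  orphan <- setdiff(day_summaries$file_key, flags$file_key)
  if (length(orphan)) {
    stop("summaries without a flag report: ", paste(orphan, collapse = ", "))
  }
  for (col in c("study_id", "participant_id", "wave")) {
    day_summaries[[col]] <- as.character(day_summaries[[col]])
    participants[[col]] <- as.character(participants[[col]])
  }
  d <- merge(day_summaries, flags, by = "file_key", sort = FALSE)
  pcols <- setdiff(names(participants), c("study_id", "participant_id", "wave"))
  d <- merge(d, participants[, c("study_id", "participant_id", "wave", pcols)],
             by = c("study_id", "participant_id", "wave"), sort = FALSE)
  orphan2 <- setdiff(day_summaries$file_key, d$file_key)
  if (length(orphan2)) {
    stop("summaries without a matching participant: ",
         paste(orphan2, collapse = ", "))
  }
  d$excluded_by_default <- d$flag %in% c("SPURIOUS", "TEMPORALLY_SHIFTED")
  # stable order so identical inputs give byte-identical output
  d <- d[order(d$pooled_id, d$study_id, d$participant_id, d$wave,
               d$file_key, d$date), , drop = FALSE]
  rownames(d) <- NULL
  attr_tab <- as.data.frame(table(flag = flags$flag), stringsAsFactors = FALSE)
  names(attr_tab) <- c("flag", "files")
  attr_tab <- attr_tab[order(attr_tab$flag), , drop = FALSE]
  rownames(attr_tab) <- NULL
  structure(list(
    data = d,
    attrition = attr_tab,
    baseline = function() {
      first_wave <- tapply(as.integer(d$wave), d$pooled_id, min)
      d[as.integer(d$wave) == first_wave[d$pooled_id], , drop = FALSE]
    }), class = "pooled_database")
}

#' @export
print.pooled_database <- function(x, ...) {
  cat(sprintf("<pooled_database> %d file-day rows, %d participants\n",
              nrow(x$data), length(unique(x$data$pooled_id))))
  print(x$attrition)
  invisible(x)
}

#' Sample-size distribution by sex and age
#'
#' @param db A `pooled_database`.
#' @param baseline_only Restrict to the earliest wave per participant.
#' @param viable_only Drop rows marked excluded-by-default.
#' @return Data frame `sex` x `age` x `n_files` (distinct file keys).
#' @export
sample_size_distribution <- function(db, baseline_only = FALSE,
                                     viable_only = TRUE) {
  d <- if (baseline_only) db$baseline() else db$data
  if (viable_only) d <- d[!d$excluded_by_default, , drop = FALSE]
  files <- unique(d[, c("file_key", "sex", "age")])
  files$age <- floor(files$age)
  out <- as.data.frame(table(sex = files$sex, age = files$age),
                       stringsAsFactors = FALSE)
  names(out)[3] <- "n_files"
  out$age <- as.integer(out$age)
  out[out$n_files > 0, , drop = FALSE]
}
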