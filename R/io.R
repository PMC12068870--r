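# Delimited-text readers/writers for annotation exports (BORIS-style event
# tables), two-stimulus trial tables, screen tables, and fluorescence trace
# tables. Comma vs tab is auto-detected from the header line. Times are
# stored internally in seconds; frame-based columns are an input dialect
# converted on read (seconds = frames / fps).

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

read_delim_auto <- function(path) {
  utils::read.table(path, header = TRUE, sep = detect_sep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "")
}

need_col <- function(df, col, what = "events table") {
  if (!col %in% names(df))
    stop(sprintf("%s is missing required column '%s'", what, col), call. = FALSE)
  df[[col]]
}

# blanks parse to NA (rows carrying no event); anything else non-numeric
# is a parse error naming the offending row(s)
parse_num <- function(x, col) {
  y <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(y) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad))
    stop(sprintf("non-numeric value in column '%s' at row(s) %s",
                 col, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  y
}

#' Default column mapping and options for event-table ingestion
#'
#' @param trial_id,genotype,condition,behavior Column names in the source
#'   table for the corresponding fields.
#' @param start,end Column names holding event times in seconds.
#' @param start_frame,end_frame Column names holding frame-based event
#'   times; used (with `fps`) when the seconds columns are absent.
#' @param fps Frame rate (Hz) used to convert frame columns to seconds.
#' @param stim_onset,stim_offset,stim_modality,duration Optional per-trial
#'   stimulus/recording metadata columns (seconds).
#' @return A named list usable as `config` in [read_events_table()].
#' @export
events_schema <- function(trial_id = "trial_id", genotype = "genotype",
                          condition = "condition", behavior = "behavior",
                          start = "start_s", end = "end_s",
                          start_frame = "start_frame", end_frame = "end_frame",
                          fps = NULL,
                          stim_onset = "stim_onset_s", stim_offset = "stim_offset_s",
                          stim_modality = "stim_modality",
                          duration = "duration_s") {
  list(trial_id = trial_id, genotype = genotype, condition = condition,
       behavior = behavior, start = start, end = end,
       start_frame = start_frame, end_frame = end_frame, fps = fps,
       stim_onset = stim_onset, stim_offset = stim_offset,
       stim_modality = stim_modality, duration = duration)
}

#' Read a behavior-annotation event table into a cohort
#'
#' Ingests a delimited text export (one row per scored behavior event) into
#' a [behavior_cohort()]. Column names are mapped through `config` (see
#' [events_schema()]); a YAML file path may be given instead of a list.
#' Times may be in seconds or in frames (converted by `fps`). Events are
#' sorted by start time within each trial.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @param config Schema mapping list from [events_schema()], or a YAML file
#'   whose keys override the defaults (e.g. `fps: 20`).
#' @param default_duration Recording duration (s) used when the table has no
#'   duration column; defaults to the latest event/stimulus time per trial.
#' @return A [behavior_cohort()].
#' @export
read_events_table <- function(path, config = events_schema(),
                              default_duration = NULL) {
  if (is.character(config) && length(config) == 1L && file.exists(config)) {
    over <- yaml::read_yaml(config)
    config <- utils::modifyList(events_schema(), over)
  }
  config <- utils::modifyList(events_schema(), config)
  df <- read_delim_auto(path)
  what <- "events table"
  trial_id <- need_col(df, config$trial_id, what)
  behavior <- need_col(df, config$behavior, what)

  if (config$start %in% names(df)) {
    start <- parse_num(df[[config$start]], config$start)
    end <- parse_num(need_col(df, config$end, what), config$end)
  } else if (config$start_frame %in% names(df)) {
    if (is.null(config$fps))
      stop("frame-based event table requires fps in config", call. = FALSE)
    start <- parse_num(df[[config$start_frame]], config$start_frame) / config$fps
    end <- parse_num(need_col(df, config$end_frame, what), config$end_frame) / config$fps
  } else {
    stop(sprintf("%s is missing required column '%s' (or '%s' with fps)",
                 what, config$start, config$start_frame), call. = FALSE)
  }

  bad <- which(end < start)
  if (length(bad))
    stop(sprintf("event end < start at row(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)

  opt <- function(col) if (col %in% names(df)) df[[col]] else NULL
  genotype <- opt(config$genotype); condition <- opt(config$condition)
  stim_on <- opt(config$stim_onset); stim_off <- opt(config$stim_offset)
  stim_mod <- opt(config$stim_modality); dur <- opt(config$duration)

  trials <- lapply(unique(trial_id), function(id) {
    sel <- trial_id == id
    ev <- data.frame(behavior = behavior[sel], start = start[sel],
                     end = end[sel], stringsAsFactors = FALSE)
    # blank rows are trial stubs (a trial with no scored events)
    ev <- ev[!(is.na(ev$start) & !nzchar(trimws(ev$behavior))), , drop = FALSE]
    if (anyNA(ev$start) || anyNA(ev$end))
      stop(sprintf("missing event time in trial %s", id), call. = FALSE)
    stim <- list()
    if (!is.null(stim_on) && !is.null(stim_off)) {
      on <- parse_num(stim_on[sel][1], config$stim_onset)
      off <- parse_num(stim_off[sel][1], config$stim_offset)
      mod <- if (!is.null(stim_mod)) stim_mod[sel][1] else "light"
      if (is.finite(on) && is.finite(off))
        stim <- list(stimulus_epoch(on, off, modality = mod))
    }
    d <- if (!is.null(dur)) parse_num(dur[sel][1], config$duration) else NA_real_
    if (!is.finite(d)) {
      d <- if (!is.null(default_duration)) default_duration else
        max(c(ev$end, vapply(stim, `[[`, numeric(1), "offset"), 0))
    }
    trial_record(id, events = ev, stimuli = stim,
                 genotype = if (is.null(genotype)) "" else genotype[sel][1],
                 condition = if (is.null(condition)) "" else condition[sel][1],
                 duration = d)
  })
  behavior_cohort(trials, metadata = list(source = path))
}

#' Write a cohort to the canonical event-table format
#'
#' One row per event with columns trial_id, genotype, condition, behavior,
#' start_s, end_s, stim_onset_s, stim_offset_s, stim_modality, duration_s.
#' Numbers are written at full double precision so that
#' [read_events_table()] round-trips field-for-field.
#'
#' @param cohort A [behavior_cohort()].
#' @param path Output file path (`.tsv` for tabs, otherwise comma).
#' @return `path`, invisibly.
#' @export
write_events_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "behavior_cohort"))
  rows <- lapply(cohort$trials, function(tr) {
    n <- max(1L, nrow(tr$events))
    ev <- if (nrow(tr$events)) tr$events else
      data.frame(behavior = "", start = NA_real_, end = NA_real_)
    st <- if (length(tr$stimuli)) tr$stimuli[[1]] else NULL
    data.frame(trial_id = tr$trial_id, genotype = tr$genotype,
               condition = tr$condition, behavior = ev$behavior,
               start_s = num17(ev$start), end_s = num17(ev$end),
               stim_onset_s = num17(if (is.null(st)) NA_real_ else st$onset),
               stim_offset_s = num17(if (is.null(st)) NA_real_ else st$offset),
               stim_modality = if (is.null(st)) "" else st$modality,
               duration_s = num17(tr$duration), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

num17 <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))

parse_bool <- function(x, col) {
  y <- tolower(trimws(x))
  out <- rep(NA, length(y))
  out[y %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[y %in% c("0", "false", "f", "no", "n")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("unparseable boolean in column '%s' at row(s) %s",
                 col, paste(bad, collapse = ", ")), call. = FALSE)
  out
}

#' Read a two-stimulus trial table
#'
#' Columns: `trial_id`, `genotype`, `responded1`, `responded2`, `interval`
#' (seconds between stimulus-1 removal and stimulus-2 delivery). Boolean
#' columns accept 0/1, true/false, yes/no case-insensitively.
#'
#' @param path Path to a comma- or tab-delimited file.
#' @return A data.frame preserving input order with canonicalized logical
#'   `responded1`/`responded2` and numeric `interval`.
#' @export
read_two_stim_table <- function(path) {
  df <- read_delim_auto(path)
  for (col in c("trial_id", "genotype", "responded1", "responded2", "interval"))
    need_col(df, col, "two-stimulus table")
  out <- data.frame(
    trial_id = df$trial_id, genotype = df$genotype,
    responded1 = parse_bool(df$responded1, "responded1"),
    responded2 = parse_bool(df$responded2, "responded2"),
    interval = parse_num(df$interval, "interval"),
    stringsAsFactors = FALSE)
  if (any(out$interval < 0))
    stop(sprintf("negative interval at row(s) %s",
                 paste(which(out$interval < 0), collapse = ", ")), call. = FALSE)
  out
}

#' Write a two-stimulus trial table
#' @param trials data.frame as returned by [read_two_stim_table()].
#' @param path Output path (`.tsv` for tabs, otherwise comma).
#' @return `path`, invisibly.
#' @export
write_two_stim_table <- function(trials, path) {
  out <- data.frame(trial_id = trials$trial_id, genotype = trials$genotype,
                    responded1 = as.integer(trials$responded1),
                    responded2 = as.integer(trials$responded2),
                    interval = num17(trials$interval))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fluorescence traces from a delimited table
#'
#' Accepts wide form (`time_s`, one column per ROI) or long form
#' (`roi`, `time_s`, `value`). Stimulus timing, named phase windows and the
#' signal kind come from a companion YAML metadata file or an equivalent
#' list with fields `stim_onset`, `stim_offset`, optional `signal_kind`
#' (`"gcamp"` or `"fura_ratio"`) and `phases` (name -> `[start, end]`).
#'
#' @param path Path to the trace table.
#' @param metadata YAML file path or list.
#' @return A named list of [fluor_trace()] objects, one per ROI.
#' @export
read_trace_table <- function(path, metadata) {
  if (is.character(metadata)) metadata <- yaml::read_yaml(metadata)
  stopifnot(is.list(metadata), !is.null(metadata$stim_onset),
            !is.null(metadata$stim_offset))
  phases <- lapply(metadata$phases, function(p) as.numeric(unlist(p)))
  kind <- if (is.null(metadata$signal_kind)) "gcamp" else metadata$signal_kind
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("roi", "time_s", "value") %in% names(df))) {
    rois <- split(df, df$roi)
    traces <- lapply(rois, function(d) {
      d <- d[order(d$time_s), ]
      fluor_trace(d$time_s, d$value, metadata$stim_onset, metadata$stim_offset,
                  signal_kind = kind, phases = phases)
    })
  } else {
    if (!"time_s" %in% names(df))
      stop("trace table must have a 'time_s' column (wide) or roi/time_s/value (long)",
           call. = FALSE)
    roi_cols <- setdiff(names(df), "time_s")
    traces <- lapply(roi_cols, function(col)
      fluor_trace(df$time_s, df[[col]], metadata$stim_onset,
                  metadata$stim_offset, signal_kind = kind, phases = phases))
    names(traces) <- roi_cols
  }
  traces
}
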