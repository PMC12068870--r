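#' Behavior event
#'
#' A single scored behavior interval (e.g. "roll", "c-bend", "hunch",
#' "freeze", "back") in seconds from recording start. Point events
#' (`end == start`) are permitted and treated as zero-duration occurrences.
#'
#' @param behavior Behavior label (non-empty string). Labels are matched
#'   case-insensitively after trimming throughout the package.
#' @param start,end Event start/end in seconds; `end >= start`, `start >= 0`.
#' @return A one-row data.frame with columns `behavior`, `start`, `end`.
#' @export
behavior_event <- function(behavior, start, end = start) {
  if (!is.character(behavior) || length(behavior) != 1L || !nzchar(trimws(behavior)))
    stop("behavior label must be a non-empty string", call. = FALSE)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end)) stop("event times must be finite", call. = FALSE)
  if (start < 0) stop("event start must be >= 0", call. = FALSE)
  if (end < start) stop("event end must be >= start", call. = FALSE)
  data.frame(behavior = behavior, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Stimulus epoch
#'
#' @param onset,offset Stimulus onset/offset in seconds; `offset > onset`.
#' @param modality One of `"light"`, `"thermal"`, `"mechanical"`.
#' @param intensity Numeric intensity (optional).
#' @param unit Free-text intensity unit, e.g. `"uW/mm2"`, `"mN"`, `"degC"`.
#' @return An object of class `stimulus_epoch`.
#' @export
stimulus_epoch <- function(onset, offset,
                           modality = c("light", "thermal", "mechanical"),
                           intensity = NA_real_, unit = "") {
  modality <- match.arg(modality)
  onset <- as.numeric(onset); offset <- as.numeric(offset)
  if (!is.finite(onset) || onset < 0) stop("stimulus onset must be >= 0", call. = FALSE)
  if (!is.finite(offset) || offset <= onset) stop("stimulus offset must be > onset", call. = FALSE)
  structure(list(onset = onset, offset = offset, modality = modality,
                 intensity = as.numeric(intensity), unit = unit),
            class = "stimulus_epoch")
}

#' @export
print.stimulus_epoch <- function(x, ...) {
  cat(sprintf("<stimulus_epoch> %s %g-%g s", x$modality, x$onset, x$offset))
  if (is.finite(x$intensity)) cat(sprintf(" @ %g %s", x$intensity, x$unit))
  cat("\n")
  invisible(x)
}

#' Trial record: one animal's annotated events plus stimulus metadata
#'
#' @param trial_id Unique trial identifier (string).
#' @param events data.frame with columns `behavior`, `start`, `end`
#'   (seconds), e.g. rbind of [behavior_event()] rows. May have zero rows.
#' @param stimuli A [stimulus_epoch()] or list of them.
#' @param genotype,condition Grouping metadata strings (e.g. `"ATR+"`).
#' @param duration Recording duration in seconds; all event and stimulus
#'   times must fall within it.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(trial_id, events = NULL, stimuli = list(),
                         genotype = "", condition = "", duration) {
  if (is.null(events))
    events <- data.frame(behavior = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(events),
            all(c("behavior", "start", "end") %in% names(events)))
  if (inherits(stimuli, "stimulus_epoch")) stimuli <- list(stimuli)
  duration <- as.numeric(duration)
  if (!is.finite(duration) || duration <= 0)
    stop("recording duration must be positive", call. = FALSE)
  events <- events[order(events$start, events$end), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(trial_id = as.character(trial_id), genotype = genotype,
                 condition = condition, events = events, stimuli = stimuli,
                 duration = duration),
            class = "trial_record")
}

#' Behavior cohort
#'
#' A set of [trial_record()]s analysed together (one optogenetic /
#' thermogenetic / mechanonociception experiment).
#'
#' @param trials List of [trial_record()] objects.
#' @param metadata Free key/value list.
#' @return An object of class `behavior_cohort`.
#' @export
behavior_cohort <- function(trials, metadata = list()) {
  if (inherits(trials, "trial_record")) trials <- list(trials)
  stopifnot(is.list(trials))
  if (!all(vapply(trials, inherits, logical(1), "trial_record")))
    stop("all elements must be trial_record objects", call. = FALSE)
  structure(list(trials = trials, metadata = metadata),
            class = "behavior_cohort")
}

#' @export
print.behavior_cohort <- function(x, ...) {
  n_ev <- sum(vapply(x$trials, function(tr) nrow(tr$events), integer(1)))
  beh <- sort(unique(unlist(lapply(x$trials, function(tr) norm_behavior(tr$events$behavior)))))
  cat(sprintf("<behavior_cohort> %d trials, %d events\n", length(x$trials), n_ev))
  if (length(beh)) cat("  behaviors:", paste(beh, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.behavior_cohort <- function(x) length(x$trials)

#' Validate a cohort against the data-model invariants
#'
#' Checks every trial for: event end >= start, non-negative times, events and
#' stimuli within the recording duration, non-empty behavior labels, and
#' duplicate trial ids. Reports issues instead of raising; never mutates
#' its input.
#'
#' @param cohort A [behavior_cohort()].
#' @return A data.frame with columns `trial_id`, `field`, `rule` (zero rows
#'   when all invariants hold).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "behavior_cohort"))
  issues <- list()
  add <- function(id, field, rule)
    issues[[length(issues) + 1L]] <<- data.frame(
      trial_id = id, field = field, rule = rule, stringsAsFactors = FALSE)
  ids <- vapply(cohort$trials, `[[`, character(1), "trial_id")
  for (id in ids[duplicated(ids)]) add(id, "trial_id", "duplicate trial_id")
  for (tr in cohort$trials) {
    ev <- tr$events
    if (nrow(ev)) {
      if (any(!nzchar(trimws(ev$behavior))))
        add(tr$trial_id, "behavior", "empty behavior label")
      if (any(ev$start < 0)) add(tr$trial_id, "start", "event start < 0")
      if (any(ev$end < ev$start)) add(tr$trial_id, "end", "event end < start")
      if (any(ev$end > tr$duration))
        add(tr$trial_id, "end", "event extends past recording_duration")
    }
    for (st in tr$stimuli) {
      if (st$offset > tr$duration)
        add(tr$trial_id, "stimuli", "stimulus extends past recording_duration")
    }
  }
  if (!length(issues))
    return(data.frame(trial_id = character(), field = character(),
                      rule = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
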