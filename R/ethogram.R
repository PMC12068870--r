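#' Proportion estimate
#'
#' A counted fraction (numerator / denominator) as used for roll
#' probabilities and responder fractions.
#'
#' @param numerator,denominator Non-negative counts, `denominator > 0`,
#'   `numerator <= denominator`.
#' @return An object of class `proportion_estimate` with fields
#'   `numerator`, `denominator`, `fraction`.
#' @export
proportion_estimate <- function(numerator, denominator) {
  if (denominator <= 0) stop("denominator must be > 0", call. = FALSE)
  if (numerator < 0 || numerator > denominator)
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  structure(list(numerator = as.integer(numerator),
                 denominator = as.integer(denominator),
                 fraction = numerator / denominator),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f\n", x$numerator, x$denominator, x$fraction))
  invisible(x)
}

#' @export
as.numeric.proportion_estimate <- function(x, ...) x$fraction

trial_events <- function(trial, behavior, strict = FALSE) {
  ev <- trial$events
  known <- unique(norm_behavior(ev$behavior))
  b <- norm_behavior(behavior)
  if (strict && !(b %in% known))
    stop(sprintf("unknown behavior label '%s' in trial %s", behavior,
                 trial$trial_id), call. = FALSE)
  ev[norm_behavior(ev$behavior) == b, , drop = FALSE]
}

#' Did a trial respond with a behavior during a window?
#'
#' TRUE iff at least one event with the given behavior overlaps the
#' half-open window `[start, end)` by a positive amount, or a zero-duration
#' event falls inside it.
#'
#' @param trial A [trial_record()].
#' @param behavior Behavior label (case-insensitive).
#' @param window Numeric `c(start, end)` in seconds.
#' @param strict If TRUE, a label absent from the trial's vocabulary is an
#'   error; default lenient mode returns FALSE.
#' @return Logical scalar.
#' @export
responded <- function(trial, behavior, window, strict = FALSE) {
  check_window(window)
  ev <- trial_events(trial, behavior, strict)
  if (!nrow(ev)) return(FALSE)
  any(event_overlaps(ev$start, ev$end, window[1], window[2]))
}

#' Response probability across a cohort
#'
#' Fraction of trials with at least one event of the behavior overlapping
#' the window (e.g. roll probability during stimulation, or rolling scored
#' in the 10 s after removal of a mechanical stimulus).
#'
#' @inheritParams responded
#' @param cohort A [behavior_cohort()].
#' @return A [proportion_estimate()].
#' @export
response_probability <- function(cohort, behavior, window, strict = FALSE) {
  stopifnot(inherits(cohort, "behavior_cohort"))
  if (!length(cohort$trials)) stop("empty cohort", call. = FALSE)
  hits <- vapply(cohort$trials, responded, logical(1),
                 behavior = behavior, window = window, strict = strict)
  proportion_estimate(sum(hits), length(hits))
}

#' Time-binned behavior fractions (ethogram matrix)
#'
#' For each behavior and each half-open time bin `[t, t + bin_width)`, the
#' fraction of trials having at least one event of that behavior
#' overlapping the bin. Default bins are 1 s wide, matching per-second
#' ethogram raster plots.
#'
#' @param cohort A [behavior_cohort()].
#' @param behaviors Character vector of behavior labels (rows).
#' @param span Numeric `c(start, end)` covered by the bins.
#' @param bin_width Bin width in seconds (> 0), default 1.
#' @return An object of class `ethogram_matrix`: list with `behaviors`,
#'   `bin_edges`, `fractions` (behaviors x bins matrix in \\[0, 1\\]), `n`.
#' @export
bin_fractions <- function(cohort, behaviors, span, bin_width = 1) {
  stopifnot(inherits(cohort, "behavior_cohort"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  check_window(span, "span")
  edges <- seq(span[1], span[2], by = bin_width)
  if (edges[length(edges)] < span[2]) edges <- c(edges, span[2])
  nb <- length(edges) - 1L
  n <- length(cohort$trials)
  frac <- matrix(0, nrow = length(behaviors), ncol = nb,
                 dimnames = list(behaviors, NULL))
  for (i in seq_along(behaviors)) {
    for (k in seq_len(nb)) {
      hits <- vapply(cohort$trials, responded, logical(1),
                     behavior = behaviors[i],
                     window = c(edges[k], edges[k + 1L]))
      frac[i, k] <- sum(hits) / n
    }
  }
  structure(list(behaviors = behaviors, bin_edges = edges,
                 fractions = frac, n = n),
            class = "ethogram_matrix")
}

#' @export
print.ethogram_matrix <- function(x, ...) {
  cat(sprintf("<ethogram_matrix> %d behaviors x %d bins, n = %d trials\n",
              length(x$behaviors), ncol(x$fractions), x$n))
  invisible(x)
}

#' Convert an ethogram matrix to a tidy table
#' @param x An `ethogram_matrix`.
#' @param ... Unused.
#' @return data.frame with behavior, bin_start, bin_end, fraction, n.
#' @export
as.data.frame.ethogram_matrix <- function(x, ...) {
  nb <- ncol(x$fractions)
  data.frame(
    behavior = rep(x$behaviors, each = nb),
    bin_start = rep(x$bin_edges[-length(x$bin_edges)], times = length(x$behaviors)),
    bin_end = rep(x$bin_edges[-1], times = length(x$behaviors)),
    fraction = as.vector(t(x$fractions)),
    n = x$n, stringsAsFactors = FALSE)
}

#' Latency to the first behavior onset after a reference time
#'
#' For each trial with at least one event of the behavior starting at or
#' after `t0` (e.g. stimulus onset), the latency to that first event's
#' start. Trials without such an event are excluded, so the result has one
#' value per responder (latency "of the larvae that rolled"). Events that
#' began before `t0` do not count as post-`t0` initiations.
#'
#' @param cohort A [behavior_cohort()].
#' @param behavior Behavior label.
#' @param t0 Reference time in seconds.
#' @return Named numeric vector of latencies (seconds), names = trial ids.
#' @export
latency_to_first <- function(cohort, behavior, t0) {
  stopifnot(inherits(cohort, "behavior_cohort"))
  out <- lapply(cohort$trials, function(tr) {
    ev <- trial_events(tr, behavior)
    starts <- ev$start[ev$start >= t0]
    if (!length(starts)) return(NULL)
    stats::setNames(min(starts) - t0, tr$trial_id)
  })
  unlist(out)
}

#' Total behavior duration per displaying trial
#'
#' For each trial showing the behavior in the window, the summed overlap of
#' that behavior's events with the window (events clipped at the window
#' edges). Trials that do not display the behavior are excluded.
#'
#' @inheritParams response_probability
#' @return Named numeric vector of total durations (s) for displayers.
#' @export
bout_durations <- function(cohort, behavior, window) {
  stopifnot(inherits(cohort, "behavior_cohort"))
  check_window(window)
  out <- lapply(cohort$trials, function(tr) {
    ev <- trial_events(tr, behavior)
    if (!nrow(ev)) return(NULL)
    keep <- event_overlaps(ev$start, ev$end, window[1], window[2])
    if (!any(keep)) return(NULL)
    tot <- sum(overlap_length(ev$start[keep], ev$end[keep], window[1], window[2]))
    stats::setNames(tot, tr$trial_id)
  })
  unlist(out)
}

#' Post-stimulus persistence of a behavior
#'
#' Fraction of all trials (not only displayers) exhibiting the behavior in
#' the window following stimulus offset.
#'
#' @param cohort A [behavior_cohort()].
#' @param behavior Behavior label.
#' @param stim A [stimulus_epoch()] (defaults to each trial's first stimulus).
#' @param post_length Length of the post window in seconds (default 10).
#' @return A [proportion_estimate()].
#' @export
post_stimulus_persistence <- function(cohort, behavior, stim = NULL,
                                      post_length = 10) {
  stopifnot(inherits(cohort, "behavior_cohort"))
  if (!length(cohort$trials)) stop("empty cohort", call. = FALSE)
  hits <- vapply(cohort$trials, function(tr) {
    st <- if (!is.null(stim)) stim else {
      if (!length(tr$stimuli))
        stop(sprintf("trial %s has no stimulus epoch", tr$trial_id), call. = FALSE)
      tr$stimuli[[1]]
    }
    responded(tr, behavior, c(st$offset, st$offset + post_length))
  }, logical(1))
  proportion_estimate(sum(hits), length(hits))
}

#' Cumulative response curve
#'
#' Fraction of trials that have responded (first overlap of the behavior
#' with `[t0, t)`) by each time point. Non-decreasing; its terminal value
#' equals [response_probability()] over the full window.
#'
#' @param cohort A [behavior_cohort()].
#' @param behavior Behavior label.
#' @param t0 Window start (e.g. stimulus onset), seconds.
#' @param t_end Window end, seconds.
#' @param resolution Sampling resolution of the curve in seconds (> 0).
#' @return data.frame with columns `time` (seconds since `t0`) and
#'   `fraction`.
#' @export
cumulative_response_curve <- function(cohort, behavior, t0, t_end,
                                      resolution = 0.1) {
  stopifnot(inherits(cohort, "behavior_cohort"))
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  check_window(c(t0, t_end))
  n <- length(cohort$trials)
  first_resp <- vapply(cohort$trials, function(tr) {
    ev <- trial_events(tr, behavior)
    if (!nrow(ev)) return(NA_real_)
    keep <- event_overlaps(ev$start, ev$end, t0, t_end)
    if (!any(keep)) return(NA_real_)
    min(pmax(ev$start[keep], t0)) - t0
  }, numeric(1))
  tt <- seq(0, t_end - t0, by = resolution)
  if (tt[length(tt)] < t_end - t0) tt <- c(tt, t_end - t0)
  frac <- vapply(tt, function(t) sum(first_resp <= t, na.rm = TRUE) / n,
                 numeric(1))
  data.frame(time = tt, fraction = frac)
}

#' Count events of a behavior overlapping a window
#'
#' @param trial A [trial_record()].
#' @param behavior Behavior label.
#' @param window Numeric `c(start, end)` seconds.
#' @return Integer count (e.g. number of rolls during stimulation).
#' @export
event_count <- function(trial, behavior, window) {
  check_window(window)
  ev <- trial_events(trial, behavior)
  if (!nrow(ev)) return(0L)
  sum(event_overlaps(ev$start, ev$end, window[1], window[2]))
}

#' Default pre/stim/post analysis windows around a stimulus epoch
#'
#' pre = `pad` s before onset, stim = onset to offset, post = `pad` s after
#' offset (10 s each by default, the scoring scheme used for optogenetic
#' trials).
#'
#' @param stim A [stimulus_epoch()].
#' @param pad Pre/post window length in seconds.
#' @return Named list of `c(start, end)` windows: `pre`, `stim`, `post`.
#' @export
default_windows <- function(stim, pad = 10) {
  list(pre = c(max(0, stim$onset - pad), stim$onset),
       stim = c(stim$onset, stim$offset),
       post = c(stim$offset, stim$offset + pad))
}
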