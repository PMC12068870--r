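# In-code fixtures and brute-force oracles used across test files.

std_stim <- function(onset = 10, offset = 20) stimulus_epoch(onset, offset, "light")

# Build a trial from a list of c(behavior, start, end) triples.
make_trial <- function(id, events = list(), stim = std_stim(), duration = 30,
                       genotype = "ctrl") {
  ev <- if (length(events)) do.call(rbind, lapply(events, function(e)
    behavior_event(e[[1]], as.numeric(e[[2]]), as.numeric(e[[3]])))) else NULL
  trial_record(id, events = ev, stimuli = stim, genotype = genotype,
               duration = duration)
}

make_cohort <- function(...) behavior_cohort(list(...))

# Cohort of n trials where the first k roll inside the window.
counted_cohort <- function(k, n, window = c(10, 20)) {
  behavior_cohort(lapply(seq_len(n), function(i) {
    evs <- if (i <= k) list(c("roll", mean(window), mean(window) + 0.5)) else list()
    make_trial(sprintf("t%03d", i), evs, duration = window[2] + 10)
  }))
}

# Random cohort for property tests: events with arbitrary overlap structure.
random_cohort <- function(n_trials, t_max = 30, behaviors = c("roll", "freeze")) {
  behavior_cohort(lapply(seq_len(n_trials), function(i) {
    n_ev <- sample(0:4, 1)
    evs <- lapply(seq_len(n_ev), function(j) {
      b <- sample(behaviors, 1)
      s <- runif(1, 0, t_max - 1)
      c(b, s, s + rexp(1, 1))
    })
    make_trial(sprintf("r%03d", i), evs, duration = t_max + 10)
  }))
}

# Brute-force interval-overlap oracle (independent of the package's
# half-open helpers): does any event of `behavior` overlap [w1, w2)?
oracle_overlaps <- function(trial, behavior, w1, w2) {
  ev <- trial$events
  ev <- ev[tolower(trimws(ev$behavior)) == tolower(trimws(behavior)), , drop = FALSE]
  if (!nrow(ev)) return(FALSE)
  any(vapply(seq_len(nrow(ev)), function(i) {
    s <- ev$start[i]; e <- ev$end[i]
    if (e > s) min(e, w2) - max(s, w1) > 0 else (s >= w1 && s < w2)
  }, logical(1)))
}

# Construct a fluor_trace from a dF/F0 function of time.
trace_from_df <- function(df_fun, f0 = 100, fps = 10, duration = 60,
                          onset = 10, offset = 20, phases = list()) {
  tt <- seq(0, duration, by = 1 / fps)
  fluor_trace(tt, f0 * (1 + df_fun(tt)), stim_onset = onset,
              stim_offset = offset, phases = phases)
}

# Two-stimulus table with exact per-interval counts (no randomness).
counted_two_stim <- function(spec) {
  # spec: data.frame(interval, r1, r2, n)
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    with(spec[i, ], data.frame(
      trial_id = sprintf("i%d_%03d", i, seq_len(n)), genotype = "ctrl",
      responded1 = seq_len(n) <= r1, responded2 = seq_len(n) <= r2,
      interval = interval, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
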