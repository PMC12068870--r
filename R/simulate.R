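# Seeded synthetic-data generators emulating each assay: behavior cohorts,
# two-stimulus sensitization experiments, screen tables, fluorescence
# traces (single transient or SOCE design), and stretch-threshold cohorts.
# All generators are pure functions of (params, seed). Per-unit substreams
# are drawn from a prefix-stable seed sequence so adding trials/cells never
# perturbs earlier ones.

#' Simulate a behavior cohort
#'
#' Each trial responds to each behavior independently with probability
#' `p_respond[behavior]`; responders get a first event starting at
#' stimulus onset plus an exponential latency (mean `latency_mean`) with
#' an exponential bout duration (mean `bout_mean`), clipped to the
#' recording.
#'
#' @param n_trials Number of trials.
#' @param p_respond Named numeric vector of per-behavior response
#'   probabilities in \\[0, 1\\] (e.g. `c(roll = 0.73)`).
#' @param stim A [stimulus_epoch()].
#' @param duration Recording duration (s); default stimulus offset + 10.
#' @param latency_mean,bout_mean Exponential means (s), > 0.
#' @param genotype Genotype label stamped on every trial.
#' @param seed Integer seed.
#' @return A [behavior_cohort()].
#' @export
gen_behavior_cohort <- function(n_trials, p_respond,
                                stim = stimulus_epoch(10, 20, "light"),
                                duration = NULL,
                                latency_mean = 1, bout_mean = 2,
                                genotype = "synthetic", seed = 1) {
  if (is.null(names(p_respond)) || any(!nzchar(names(p_respond))))
    stop("p_respond must be a named vector (behavior -> probability)", call. = FALSE)
  if (any(p_respond < 0 | p_respond > 1))
    stop("response probabilities must lie in [0, 1]", call. = FALSE)
  if (latency_mean <= 0 || bout_mean <= 0)
    stop("latency_mean and bout_mean must be > 0", call. = FALSE)
  if (is.null(duration)) duration <- stim$offset + 10
  seeds <- substream_seeds(seed, n_trials)
  trials <- lapply(seq_len(n_trials), function(i) {
    with_seed(seeds[i], {
      evs <- list()
      for (b in names(p_respond)) {
        if (stats::runif(1) < p_respond[[b]]) {
          start <- min(stim$onset + stats::rexp(1, 1 / latency_mean),
                       duration)
          end <- min(start + stats::rexp(1, 1 / bout_mean), duration)
          evs[[length(evs) + 1L]] <- behavior_event(b, start, end)
        }
      }
      ev <- if (length(evs)) do.call(rbind, evs) else NULL
      trial_record(sprintf("T%04d", i), events = ev, stimuli = stim,
                   genotype = genotype, duration = duration)
    })
  })
  behavior_cohort(trials, metadata = list(seed = seed))
}

#' Simulate a two-stimulus sensitization experiment
#'
#' For each recovery interval t, `responded1 ~ Bernoulli(P1)` and
#' `responded2 ~ Bernoulli(P1 + E0 * exp(-t / tau))`: the enhancement of
#' the second response decays exponentially with the recovery time.
#'
#' @param P1 Baseline response probability to stimulus 1.
#' @param E0 Initial enhancement at zero recovery; `P1 + E0 <= 1`.
#' @param tau Decay time constant of sensitization (s, > 0).
#' @param intervals Recovery intervals (s).
#' @param n_per_interval Trials per interval.
#' @param genotype Genotype label.
#' @param seed Integer seed.
#' @return Two-stimulus trial data.frame (`trial_id`, `genotype`,
#'   `responded1`, `responded2`, `interval`).
#' @export
gen_two_stim_experiment <- function(P1, E0, tau,
                                    intervals = c(10, 60, 180, 420, 900),
                                    n_per_interval = 30,
                                    genotype = "synthetic", seed = 1) {
  if (P1 < 0 || E0 < 0 || P1 + E0 > 1)
    stop("require 0 <= P1, 0 <= E0, P1 + E0 <= 1", call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  n <- length(intervals) * n_per_interval
  seeds <- substream_seeds(seed, n)
  rows <- vector("list", n)
  k <- 0L
  for (t in intervals) {
    p2 <- P1 + E0 * exp(-t / tau)
    for (j in seq_len(n_per_interval)) {
      k <- k + 1L
      rows[[k]] <- with_seed(seeds[k], data.frame(
        trial_id = sprintf("S%05d", k), genotype = genotype,
        responded1 = stats::runif(1) < P1,
        responded2 = stats::runif(1) < p2,
        interval = t, stringsAsFactors = FALSE))
    }
  }
  do.call(rbind, rows)
}

#' Simulate a screen table of potentiation indices
#'
#' Background genotypes draw indices from Normal(mu0, background_sd);
#' planted genotypes are offset by the stated effect (in index units).
#'
#' @param n_genotypes Number of genotypes (>= 3).
#' @param background_sd SD of the background index distribution (> 0).
#' @param mu0 Background mean index.
#' @param planted Named numeric vector genotype -> additive effect; names
#'   must be genotype labels `g01`, `g02`, ... or new labels appended.
#' @param seed Integer seed.
#' @return data.frame `genotype`, `index`, `planted` (logical).
#' @export
gen_screen <- function(n_genotypes, background_sd, mu0 = 0,
                       planted = NULL, seed = 1) {
  if (n_genotypes < 3L) stop("need >= 3 genotypes", call. = FALSE)
  if (background_sd <= 0) stop("background_sd must be > 0", call. = FALSE)
  genos <- sprintf("g%02d", seq_len(n_genotypes))
  seeds <- substream_seeds(seed, n_genotypes)
  idx <- vapply(seq_len(n_genotypes), function(i)
    with_seed(seeds[i], stats::rnorm(1, mu0, background_sd)), numeric(1))
  is_planted <- rep(FALSE, n_genotypes)
  if (!is.null(planted)) {
    for (g in names(planted)) {
      j <- match(g, genos)
      if (is.na(j)) stop(sprintf("planted genotype '%s' not in screen", g),
                         call. = FALSE)
      idx[j] <- idx[j] + planted[[g]]
      is_planted[j] <- TRUE
    }
  }
  data.frame(genotype = genos, index = idx, planted = is_planted,
             stringsAsFactors = FALSE)
}

#' Simulate a fluorescence trace
#'
#' Baseline `f0` plus a stimulus-locked double-exponential transient:
#' `F(t) = f0 * (1 + A * (1 - exp(-(t - onset)/rise_tau)) *
#' exp(-(t - onset)/decay_tau))` for `t >= onset`, with additive Gaussian
#' noise. With `soce` set, instead emits a three-phase store-operated
#' calcium entry design: baseline, a store-release bump inside a
#' `zero_ca` phase, and a re-entry bump inside a `ca_readdition` phase,
#' each a double-exponential transient with its own amplitude; an
#' `ionomycin` phase with a large terminal response is appended.
#'
#' @param f0 Baseline fluorescence (a.u., > 0).
#' @param amplitude Transient amplitude in dF/F0 units.
#' @param onset Stimulus onset (s).
#' @param rise_tau,decay_tau Rise/decay time constants (s).
#' @param fps Sampling rate (Hz).
#' @param duration Recording length (s), > onset.
#' @param noise_sd Gaussian noise SD (a.u., >= 0).
#' @param stim_length Stimulus window length (s).
#' @param soce Optional list with `store_amplitude`, `reentry_amplitude`,
#'   optional `ionomycin_amplitude` (dF/F0 units) to produce a SOCE trace.
#' @param seed Integer seed.
#' @return A [fluor_trace()] with attribute `"truth"` holding the
#'   generating parameters.
#' @export
gen_trace <- function(f0 = 100, amplitude = 0.5, onset = 10,
                      rise_tau = 0.5, decay_tau = 5, fps = 10,
                      duration = 60, noise_sd = 0, stim_length = 10,
                      soce = NULL, seed = 1) {
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (duration <= onset) stop("duration must exceed onset", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (f0 <= 0) stop("f0 must be > 0", call. = FALSE)
  times <- seq(0, duration, by = 1 / fps)
  bump <- function(t, t0, A) {
    s <- t - t0
    ifelse(s >= 0, A * (1 - exp(-s / rise_tau)) * exp(-s / decay_tau), 0)
  }
  phases <- list()
  if (is.null(soce)) {
    df <- bump(times, onset, amplitude)
    stim_off <- min(onset + stim_length, duration)
  } else {
    # thirds: zero-calcium store release, calcium re-addition, ionomycin
    seg <- (duration - onset) / 3
    phases <- list(zero_ca = c(onset, onset + seg),
                   ca_readdition = c(onset + seg, onset + 2 * seg),
                   ionomycin = c(onset + 2 * seg, duration))
    iono_amp <- if (is.null(soce$ionomycin_amplitude)) 1 else soce$ionomycin_amplitude
    df <- bump(times, onset, soce$store_amplitude) +
      bump(times, onset + seg, soce$reentry_amplitude) +
      bump(times, onset + 2 * seg, iono_amp)
    stim_off <- onset + seg
  }
  noise <- if (noise_sd > 0) with_seed(seed, stats::rnorm(length(times), 0, noise_sd)) else 0
  values <- f0 * (1 + df) + noise
  tr <- fluor_trace(times, values, stim_onset = onset, stim_offset = stim_off,
                    phases = phases)
  attr(tr, "truth") <- list(f0 = f0, amplitude = amplitude, onset = onset,
                            rise_tau = rise_tau, decay_tau = decay_tau,
                            noise_sd = noise_sd, soce = soce, seed = seed)
  tr
}

#' Closed-form peak of the double-exponential transient
#'
#' For `g(s) = A (1 - e^(-s/r)) e^(-s/d)`, the peak lies at
#' `s* = r log((r + d)/r)` with value
#' `A * d/(r+d) * ((r+d)/r)^(-r/d)`.
#'
#' @param amplitude,rise_tau,decay_tau Transient parameters.
#' @return List with `time` (s after onset) and `value` (dF/F0).
#' @export
transient_peak <- function(amplitude, rise_tau, decay_tau) {
  r <- rise_tau; d <- decay_tau
  s <- r * log((r + d) / r)
  list(time = s,
       value = amplitude * (d / (r + d)) * ((r + d) / r)^(-r / d))
}

#' Simulate a stretch-threshold cohort
#'
#' Each cell draws a stretch threshold from a categorical distribution
#' over the tested magnitudes plus "never", and responds at all
#' magnitudes >= its threshold.
#'
#' @param threshold_probs Named numeric vector over
#'   `c(as.character(magnitudes), "never")`, summing to 1.
#' @param n_cells Number of cells.
#' @param magnitudes Increasing stretch magnitudes (%).
#' @param seed Integer seed.
#' @return A [stretch_series()] with attribute `"truth"`.
#' @export
gen_stretch_cohort <- function(threshold_probs, n_cells,
                               magnitudes = c(0.5, 1, 2.5, 5), seed = 1) {
  labels <- c(as.character(magnitudes), "never")
  if (!setequal(names(threshold_probs), labels))
    stop("threshold_probs must be named over the magnitudes plus 'never'",
         call. = FALSE)
  p <- as.numeric(threshold_probs[labels])
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("threshold_probs must be non-negative and sum to 1", call. = FALSE)
  seeds <- substream_seeds(seed, n_cells)
  draw <- vapply(seq_len(n_cells), function(i)
    with_seed(seeds[i], sample.int(length(labels), 1L, prob = p)), integer(1))
  resp <- matrix(FALSE, n_cells, length(magnitudes))
  for (i in seq_len(n_cells)) {
    if (draw[i] <= length(magnitudes))
      resp[i, draw[i]:length(magnitudes)] <- TRUE
  }
  out <- stretch_series(magnitudes, resp)
  attr(out, "truth") <- list(threshold_probs = threshold_probs, seed = seed)
  out
}
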