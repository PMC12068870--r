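#' Fluorescence trace for one ROI
#'
#' A sampled fluorescence time series (GCaMP intensity or Fura-2 340/380
#' ratio) with stimulus timing and optional named phase windows (e.g.
#' `zero_ca`, `ca_readdition`, `ionomycin` for store-operated calcium
#' entry assays).
#'
#' @param times Strictly increasing sample times (seconds).
#' @param values Fluorescence values (a.u. or ratio), same length,
#'   length >= 3.
#' @param stim_onset,stim_offset Stimulus window (seconds),
#'   `stim_onset < stim_offset`.
#' @param signal_kind `"gcamp"` or `"fura_ratio"`.
#' @param phases Named list of `c(start, end)` windows; must be pairwise
#'   disjoint.
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(times, values, stim_onset, stim_offset,
                        signal_kind = c("gcamp", "fura_ratio"),
                        phases = list()) {
  signal_kind <- match.arg(signal_kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) || length(times) < 3L)
    stop("times and values must have equal length >= 3", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (stim_onset >= stim_offset) stop("stim_onset must be < stim_offset", call. = FALSE)
  if (length(phases)) {
    if (is.null(names(phases)) || any(!nzchar(names(phases))))
      stop("phase windows must be named", call. = FALSE)
    ivs <- do.call(rbind, lapply(phases, function(p) as.numeric(p[1:2])))
    ord <- order(ivs[, 1])
    ivs <- ivs[ord, , drop = FALSE]
    if (any(ivs[, 2] <= ivs[, 1])) stop("phase windows must have end > start", call. = FALSE)
    if (nrow(ivs) > 1 && any(ivs[-1, 1] < ivs[-nrow(ivs), 2]))
      stop("phase windows overlap", call. = FALSE)
  }
  structure(list(times = times, values = values, stim_onset = stim_onset,
                 stim_offset = stim_offset, signal_kind = signal_kind,
                 phases = phases),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %s, %d samples over %g-%g s, stim %g-%g s\n",
              x$signal_kind, length(x$times), min(x$times), max(x$times),
              x$stim_onset, x$stim_offset))
  if (length(x$phases))
    cat("  phases:", paste(names(x$phases), collapse = ", "), "\n")
  invisible(x)
}

#' Assay configuration: baseline window, responder threshold, viability rule
#'
#' Presets follow the imaging conventions of each preparation: axon-terminal
#' imaging uses a 10-frame pre-stimulus baseline; dissociated-cell imaging
#' uses 5 frames. Responder thresholds (percent increase over baseline,
#' strict `>`): 10 for fillet poke, 5 for stretch/flow/osmotic, 15 for
#' Fura-2 ratio traces. Viability rules gate on an ionomycin phase:
#' `gcamp_10pct` requires a > 10% peak increase; `fura_10sd` requires a
#' peak more than 10 baseline SDs above the baseline mean.
#'
#' @param assay Preset name, or `"custom"` to use the other arguments
#'   as given.
#' @param baseline_frames Number of pre-stimulus frames averaged for F0.
#' @param responder_threshold_pct Percent-increase responder threshold
#'   (> 0).
#' @param viability_rule `"none"`, `"gcamp_10pct"` or `"fura_10sd"`.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(assay = c("custom", "axon_terminal", "fillet_poke",
                                   "dissociated_stretch", "hacat_fura"),
                         baseline_frames = 10,
                         responder_threshold_pct = 10,
                         viability_rule = c("none", "gcamp_10pct", "fura_10sd")) {
  assay <- match.arg(assay)
  viability_rule <- match.arg(viability_rule)
  preset <- switch(assay,
    axon_terminal       = list(baseline_frames = 10, responder_threshold_pct = 10,
                               viability_rule = "none"),
    fillet_poke         = list(baseline_frames = 10, responder_threshold_pct = 10,
                               viability_rule = "none"),
    dissociated_stretch = list(baseline_frames = 5, responder_threshold_pct = 5,
                               viability_rule = "gcamp_10pct"),
    hacat_fura          = list(baseline_frames = 5, responder_threshold_pct = 15,
                               viability_rule = "fura_10sd"),
    custom              = list(baseline_frames = baseline_frames,
                               responder_threshold_pct = responder_threshold_pct,
                               viability_rule = viability_rule))
  if (preset$baseline_frames < 1) stop("baseline_frames must be >= 1", call. = FALSE)
  if (preset$responder_threshold_pct <= 0)
    stop("responder threshold must be > 0", call. = FALSE)
  structure(c(preset, list(assay = assay)), class = "assay_config")
}

#' @export
print.assay_config <- function(x, ...) {
  cat(sprintf("<assay_config> %s: F0 over %d frames, responder > %g%%, viability %s\n",
              x$assay, x$baseline_frames, x$responder_threshold_pct,
              x$viability_rule))
  invisible(x)
}

#' Baseline fluorescence F0
#'
#' Arithmetic mean of the last `baseline_frames` samples strictly before
#' stimulus onset. Errors when fewer pre-stimulus samples exist or the
#' resulting F0 is not positive (normalization would be meaningless).
#'
#' @param trace A [fluor_trace()].
#' @param config An [assay_config()].
#' @return Numeric F0.
#' @export
baseline_f0 <- function(trace, config = assay_config()) {
  pre <- which(trace$times < trace$stim_onset)
  if (length(pre) < config$baseline_frames)
    stop(sprintf("only %d pre-stimulus samples; need %d for the baseline",
                 length(pre), config$baseline_frames), call. = FALSE)
  idx <- utils::tail(pre, config$baseline_frames)
  f0 <- mean(trace$values[idx])
  if (f0 <= 0) stop("baseline F0 must be > 0 for normalization", call. = FALSE)
  f0
}

#' Normalize a trace to F/F0 (and dF/F0)
#'
#' @param trace A [fluor_trace()].
#' @param f0 Baseline from [baseline_f0()] (> 0).
#' @return data.frame with `time`, `f_over_f0`, `df_over_f0`
#'   (= `f_over_f0 - 1`).
#' @export
normalize_trace <- function(trace, f0) {
  if (f0 <= 0) stop("f0 must be > 0", call. = FALSE)
  r <- trace$values / f0
  data.frame(time = trace$times, f_over_f0 = r, df_over_f0 = r - 1)
}

window_idx <- function(trace, window) {
  idx <- which(trace$times >= window[1] & trace$times <= window[2])
  if (!length(idx)) stop("window contains no samples", call. = FALSE)
  idx
}

#' Peak normalized response F_max / F0
#'
#' Maximum of F/F0 within a window (default: stimulus onset to recording
#' end). Ties resolve to the earliest sample, whose time is attached as
#' attribute `"peak_time"`.
#'
#' @param trace A [fluor_trace()].
#' @param f0 Baseline value.
#' @param window `c(start, end)` seconds; default onset -> end.
#' @return Numeric F_max/F0 with attribute `peak_time`.
#' @export
peak_ratio <- function(trace, f0, window = NULL) {
  if (is.null(window)) window <- c(trace$stim_onset, max(trace$times))
  if (window[1] > max(trace$times) || window[2] < min(trace$times))
    stop("window lies outside the recording", call. = FALSE)
  idx <- window_idx(trace, window)
  vals <- trace$values[idx] / f0
  k <- which.max(vals)
  structure(vals[k], peak_time = trace$times[idx][k])
}

#' Trapezoidal area under the dF/F0 curve
#'
#' Integral of `dF/F0 = F/F0 - 1` over a window (default: stimulus onset
#' to offset) by the trapezoidal rule on the actual sample times. Window
#' endpoints are snapped to the nearest enclosed samples; no
#' extrapolation.
#'
#' @param trace A [fluor_trace()].
#' @param f0 Baseline value.
#' @param window `c(start, end)` seconds; default stimulus window.
#' @return Numeric AUC in (dF/F0) x seconds.
#' @export
trace_auc <- function(trace, f0, window = NULL) {
  if (is.null(window)) window <- c(trace$stim_onset, trace$stim_offset)
  idx <- which(trace$times >= window[1] & trace$times <= window[2])
  if (length(idx) < 2L) stop("need >= 2 samples inside the window", call. = FALSE)
  pracma::trapz(trace$times[idx], trace$values[idx] / f0 - 1)
}

#' Response duration: total time above the responder threshold
#'
#' Total time the normalized signal spends with
#' `dF/F0 > responder_threshold_pct / 100`, with threshold crossings
#' located by linear interpolation between samples. This is the duration
#' convention used for calcium-transient summaries; the criterion is
#' configurable via `config`.
#'
#' @param trace A [fluor_trace()].
#' @param f0 Baseline value.
#' @param config An [assay_config()] supplying the threshold.
#' @return Duration in seconds (0 when never above threshold).
#' @export
response_duration <- function(trace, f0, config = assay_config()) {
  thr <- config$responder_threshold_pct / 100
  t <- trace$times
  y <- trace$values / f0 - 1 - thr   # positive while above threshold
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    y1 <- y[i]; y2 <- y[i + 1L]; dt <- t[i + 1L] - t[i]
    if (y1 > 0 && y2 > 0) total <- total + dt
    else if (y1 > 0 && y2 <= 0) total <- total + dt * y1 / (y1 - y2)
    else if (y1 <= 0 && y2 > 0) total <- total + dt * y2 / (y2 - y1)
  }
  total
}

#' Responder classification by percent increase over baseline
#'
#' A trace is a responder iff `100 * (F_max/F0 - 1)` strictly exceeds the
#' assay's threshold. When a viability gate applies and the cell is not
#' viable, the responder call is forced FALSE and flagged `gated`.
#'
#' @param fmax_over_f0 Peak ratio from [peak_ratio()].
#' @param config An [assay_config()].
#' @param viable Viability from [viability_gate()] (TRUE when no gate).
#' @return Logical; attribute `gated` is TRUE when forced by viability.
#' @export
classify_responder <- function(fmax_over_f0, config = assay_config(),
                               viable = TRUE) {
  if (!isTRUE(viable))
    return(structure(FALSE, gated = TRUE))
  pct <- 100 * (as.numeric(fmax_over_f0) - 1)
  # strict >, with an absolute guard so that a peak exactly at the
  # threshold never classifies as a responder through roundoff
  structure(pct - config$responder_threshold_pct > 1e-9, gated = FALSE)
}

#' Ionomycin viability gate
#'
#' Only cells responding to an end-of-session ionomycin perfusion enter
#' analysis. `gcamp_10pct`: peak percent increase within the `ionomycin`
#' phase must exceed 10% of baseline. `fura_10sd`: the peak within the
#' phase must exceed the baseline mean by more than 10 baseline standard
#' deviations (ratio units).
#'
#' @param trace A [fluor_trace()] with an `ionomycin` phase window (when
#'   the rule is not `"none"`).
#' @param config An [assay_config()] supplying `viability_rule` and the
#'   baseline window.
#' @return Logical viability.
#' @export
viability_gate <- function(trace, config = assay_config()) {
  if (config$viability_rule == "none") return(TRUE)
  if (!"ionomycin" %in% names(trace$phases))
    stop("viability gating requires an 'ionomycin' phase window", call. = FALSE)
  win <- trace$phases[["ionomycin"]]
  idx <- window_idx(trace, win)
  pre <- which(trace$times < trace$stim_onset)
  if (length(pre) < config$baseline_frames)
    stop("too few pre-stimulus samples for the viability baseline", call. = FALSE)
  bidx <- utils::tail(pre, config$baseline_frames)
  base <- trace$values[bidx]
  peak <- max(trace$values[idx])
  switch(config$viability_rule,
    gcamp_10pct = 100 * (peak / mean(base) - 1) > 10,
    fura_10sd = peak > mean(base) + 10 * stats::sd(base))
}

#' Store-operated calcium entry (SOCE) phase metrics
#'
#' Decomposes a SOCE assay trace into its store-release phase (stimulation
#' in zero extracellular calcium, phase `zero_ca`) and calcium re-addition
#' phase (`ca_readdition`), integrating dF/F0 over each by the trapezoidal
#' rule. A cell is store-dominant when its store-release AUC strictly
#' exceeds its re-entry AUC.
#'
#' @param trace A [fluor_trace()] with disjoint `zero_ca` and
#'   `ca_readdition` phases.
#' @param f0 Baseline value (default: computed with `config`).
#' @param config An [assay_config()] for the baseline window.
#' @return List of class `soce_metrics`: `store_auc`, `reentry_auc`,
#'   `store_dominant`.
#' @export
soce_phase_metrics <- function(trace, f0 = NULL, config = assay_config("dissociated_stretch")) {
  for (ph in c("zero_ca", "ca_readdition"))
    if (!ph %in% names(trace$phases))
      stop(sprintf("trace is missing the '%s' phase window", ph), call. = FALSE)
  if (is.null(f0)) f0 <- baseline_f0(trace, config)
  store <- trace_auc(trace, f0, window = trace$phases[["zero_ca"]])
  reentry <- trace_auc(trace, f0, window = trace$phases[["ca_readdition"]])
  structure(list(store_auc = store, reentry_auc = reentry,
                 store_dominant = store > reentry),
            class = "soce_metrics")
}

#' @export
print.soce_metrics <- function(x, ...) {
  cat(sprintf("<soce_metrics> store AUC %.4g, re-entry AUC %.4g -> %s\n",
              x$store_auc, x$reentry_auc,
              if (x$store_dominant) "store-dominant" else "re-entry-dominant"))
  invisible(x)
}

#' Per-trace metric summary
#'
#' Computes the standard per-ROI metric set: F0, peak F_max/F0, percent
#' increase, AUC over the stimulus window, response duration, decay fit
#' from the peak, viability and responder call.
#'
#' @param trace A [fluor_trace()].
#' @param config An [assay_config()].
#' @param fit_decay Fit the peak-to-end decay (default TRUE).
#' @param peak_window Optional window for the peak search (default onset
#'   to recording end).
#' @return List of class `trace_metrics` with fields `f0`, `fmax_over_f0`,
#'   `pct_increase`, `auc`, `duration`, `decay` (a `decay_fit` or NULL),
#'   `viable`, `responder`.
#' @export
trace_metrics <- function(trace, config = assay_config(), fit_decay = TRUE,
                          peak_window = NULL) {
  f0 <- baseline_f0(trace, config)
  fmax <- peak_ratio(trace, f0, window = peak_window)
  viable <- viability_gate(trace, config)
  resp <- classify_responder(fmax, config, viable = viable)
  decay <- NULL
  if (fit_decay) {
    idx <- which(trace$times >= trace$stim_onset)
    decay <- tryCatch(
      decay_fit_from_trace(trace$times[idx], trace$values[idx] / f0 - 1),
      error = function(e) NULL)
  }
  structure(list(f0 = f0, fmax_over_f0 = as.numeric(fmax),
                 peak_time = attr(fmax, "peak_time"),
                 pct_increase = 100 * (as.numeric(fmax) - 1),
                 auc = trace_auc(trace, f0),
                 duration = response_duration(trace, f0, config),
                 decay = decay, viable = viable,
                 responder = as.logical(resp), gated = attr(resp, "gated")),
            class = "trace_metrics")
}

#' @export
print.trace_metrics <- function(x, ...) {
  cat(sprintf("<trace_metrics> F0 %.4g | Fmax/F0 %.4g (+%.2f%%) | AUC %.4g | dur %.3g s\n",
              x$f0, x$fmax_over_f0, x$pct_increase, x$auc, x$duration))
  cat(sprintf("  responder: %s, viable: %s", x$responder, x$viable))
  if (!is.null(x$decay) && is.finite(x$decay$tau))
    cat(sprintf(", decay tau %.4g s (R^2 %.3f)", x$decay$tau, x$decay$r_squared))
  cat("\n")
  invisible(x)
}

#' Metrics table for a list of traces
#'
#' @param traces Named list of [fluor_trace()] (e.g. from
#'   [read_trace_table()]).
#' @inheritParams trace_metrics
#' @return data.frame, one row per ROI, with columns `roi`, `f0`,
#'   `fmax_over_f0`, `pct_increase`, `auc`, `duration`, `tau`,
#'   `r_squared`, `responder`, `viable`.
#' @export
cohort_trace_metrics <- function(traces, config = assay_config(),
                                 fit_decay = TRUE) {
  rows <- lapply(seq_along(traces), function(i) {
    m <- trace_metrics(traces[[i]], config, fit_decay = fit_decay)
    data.frame(roi = if (!is.null(names(traces))) names(traces)[i] else as.character(i),
               f0 = m$f0, fmax_over_f0 = m$fmax_over_f0,
               pct_increase = m$pct_increase, auc = m$auc,
               duration = m$duration,
               tau = if (!is.null(m$decay)) m$decay$tau else NA_real_,
               r_squared = if (!is.null(m$decay)) m$decay$r_squared else NA_real_,
               responder = m$responder, viable = m$viable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of traces/cells satisfying a predicate
#'
#' @param x List of metric objects (or any list), or a logical vector.
#' @param predicate Function mapping an element to TRUE/FALSE (ignored when
#'   `x` is already logical).
#' @return A [proportion_estimate()].
#' @export
cohort_fraction <- function(x, predicate = NULL) {
  if (is.logical(x)) hits <- x
  else {
    if (!length(x)) stop("empty cohort", call. = FALSE)
    hits <- vapply(x, function(el) isTRUE(predicate(el)), logical(1))
  }
  if (!length(hits)) stop("empty cohort", call. = FALSE)
  proportion_estimate(sum(hits), length(hits))
}
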