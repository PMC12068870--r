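# Orchestration layer: each run_* function reads delimited inputs, applies
# the corresponding analyses, and writes tidy delimited tables plus a
# report of the effective configuration. These back the command-line
# dispatcher in inst/scripts/epinoci.R; results are identical to calling
# the underlying functions directly.

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) fmt_num(x))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_config_report <- function(out_dir, config) {
  config$package_version <- as.character(utils::packageVersion("epinoci"))
  yaml::write_yaml(config, file.path(out_dir, "run_config.yaml"))
}

#' Run the ethogram analysis on an events table
#'
#' Writes five tables to `out_dir`: response probability, 1-s binned
#' behavior fractions, latencies, bout durations, and post-stimulus
#' persistence, plus the effective configuration.
#'
#' @param events_file Event table path (see [read_events_table()]).
#' @param out_dir Output directory (created if needed).
#' @param behaviors Behavior labels to summarize; default: all in cohort.
#' @param response_behavior Behavior used for the response probability
#'   (default `"roll"`).
#' @param windows Optional named list of `c(start, end)` windows; default
#'   [default_windows()] around each trial's first stimulus.
#' @param bin_width Ethogram bin width (s).
#' @param post_length Post-stimulus persistence window length (s).
#' @param schema Schema config for [read_events_table()].
#' @return Invisibly, the list of output paths.
#' @export
run_ethogram <- function(events_file, out_dir, behaviors = NULL,
                         response_behavior = "roll", windows = NULL,
                         bin_width = 1, post_length = 10,
                         schema = events_schema()) {
  cohort <- read_events_table(events_file, schema)
  issues <- validate_cohort(cohort)
  if (nrow(issues))
    stop("events table failed validation: ",
         paste(sprintf("[%s] %s", issues$trial_id, issues$rule), collapse = "; "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(behaviors))
    behaviors <- sort(unique(unlist(lapply(cohort$trials,
                                           function(tr) norm_behavior(tr$events$behavior)))))
  stim <- cohort$trials[[1]]$stimuli
  if (is.null(windows)) {
    if (!length(stim)) stop("no stimulus metadata; supply windows", call. = FALSE)
    windows <- default_windows(stim[[1]], pad = post_length)
  }
  span <- c(windows$pre[1], windows$post[2])

  rp <- response_probability(cohort, response_behavior, windows$stim)
  eth <- bin_fractions(cohort, behaviors, span = span, bin_width = bin_width)
  lat <- latency_to_first(cohort, response_behavior, t0 = windows$stim[1])
  paths <- list()
  p <- function(name) file.path(out_dir, name)

  write_tsv(data.frame(behavior = response_behavior,
                       window_start = windows$stim[1], window_end = windows$stim[2],
                       responders = rp$numerator, n = rp$denominator,
                       fraction = rp$fraction), paths$response <- p("response_probability.tsv"))
  write_tsv(as.data.frame(eth), paths$ethogram <- p("ethogram_bins.tsv"))
  write_tsv(data.frame(trial_id = names(lat), latency_s = unname(lat)),
            paths$latency <- p("latency.tsv"))
  dur_rows <- lapply(behaviors, function(b) {
    d <- bout_durations(cohort, b, windows$stim)
    if (is.null(d)) return(NULL)
    data.frame(trial_id = names(d), behavior = b, duration_s = unname(d))
  })
  dd <- do.call(rbind, dur_rows)
  if (is.null(dd)) dd <- data.frame(trial_id = character(), behavior = character(),
                                    duration_s = numeric())
  write_tsv(dd, paths$durations <- p("bout_durations.tsv"))
  pers_rows <- lapply(behaviors, function(b) {
    pe <- post_stimulus_persistence(cohort, b, post_length = post_length)
    data.frame(behavior = b, responders = pe$numerator, n = pe$denominator,
               fraction = pe$fraction)
  })
  write_tsv(do.call(rbind, pers_rows), paths$persistence <- p("persistence.tsv"))
  write_config_report(out_dir, list(
    subcommand = "ethogram", events_file = events_file,
    response_behavior = response_behavior, behaviors = behaviors,
    windows = lapply(windows, as.numeric), bin_width = bin_width,
    post_length = post_length))
  invisible(paths)
}

#' Run the sensitization analysis on a two-stimulus table
#'
#' Computes the potentiation summary, the per-interval enhancement
#' recovery curve, and (with >= 3 intervals) the exponential decay fit of
#' enhancement vs recovery time.
#'
#' @param two_stim_file Two-stimulus table path ([read_two_stim_table()]).
#' @param out_dir Output directory.
#' @param pooled_p1 Pool the first-stimulus probability across intervals.
#' @return Invisibly, a list with `curve` (data.frame) and `fit`
#'   (`decay_fit` or NULL).
#' @export
run_sensitization <- function(two_stim_file, out_dir, pooled_p1 = FALSE) {
  trials <- read_two_stim_table(two_stim_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curve <- recovery_curve(trials, pooled_p1 = pooled_p1)
  write_tsv(curve, file.path(out_dir, "recovery_curve.tsv"))
  fit <- NULL
  if (nrow(curve) >= 3L) {
    fit <- fit_exponential_decay(curve$interval, curve$enhancement)
    writeLines(c(
      "exponential decay fit: y = a * exp(b * t)",
      sprintf("a\t%s", fmt_num(fit$a)),
      sprintf("b_per_s\t%s", fmt_num(fit$b)),
      sprintf("tau_s\t%s", fmt_num(fit$tau)),
      sprintf("r_squared\t%s", fmt_num(fit$r_squared)),
      sprintf("reliable\t%s", fit$reliable),
      sprintf("points_used\t%d", fit$points_used)),
      file.path(out_dir, "decay_fit.txt"))
  }
  write_config_report(out_dir, list(subcommand = "sensitization",
                                    two_stim_file = two_stim_file,
                                    pooled_p1 = pooled_p1))
  invisible(list(curve = curve, fit = fit))
}

#' Run the screen z-score procedure on a counts table
#'
#' @param screen_file Table with columns `genotype`, `rollers1`, `n1`,
#'   `rollers2`, `n2` (or `genotype`, `index`).
#' @param out_dir Output directory.
#' @param z_cut Hit threshold on `|z|` (default 2).
#' @return Invisibly, the annotated screen data.frame.
#' @export
run_screen <- function(screen_file, out_dir, z_cut = 2) {
  df <- read_delim_auto(screen_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (all(c("rollers1", "n1", "rollers2", "n2") %in% names(df))) {
    for (col in c("rollers1", "n1", "rollers2", "n2"))
      df[[col]] <- parse_num(df[[col]], col)
    out <- screen_from_counts(df, z_cut = z_cut)
  } else {
    df$index <- parse_num(need_col(df, "index", "screen table"), "index")
    out <- screen_zscores(df[, c("genotype", "index")], z_cut = z_cut)
  }
  write_tsv(out, file.path(out_dir, "screen_results.tsv"))
  write_config_report(out_dir, list(subcommand = "screen",
                                    screen_file = screen_file, z_cut = z_cut))
  invisible(out)
}

#' Run the calcium-trace metric pipeline
#'
#' @param trace_file Trace table path ([read_trace_table()]).
#' @param metadata_file Companion YAML metadata path.
#' @param out_dir Output directory.
#' @param config An [assay_config()] (or preset name).
#' @return Invisibly, the per-ROI metrics data.frame.
#' @export
run_calcium <- function(trace_file, metadata_file, out_dir,
                        config = assay_config()) {
  if (is.character(config)) config <- assay_config(config)
  if (config$responder_threshold_pct <= 0)
    stop("responder threshold must be > 0", call. = FALSE)
  traces <- read_trace_table(trace_file, metadata_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  met <- cohort_trace_metrics(traces, config)
  has_soce <- all(c("zero_ca", "ca_readdition") %in% names(traces[[1]]$phases))
  if (has_soce) {
    soce <- lapply(traces, soce_phase_metrics, config = config)
    met$store_auc <- vapply(soce, `[[`, numeric(1), "store_auc")
    met$reentry_auc <- vapply(soce, `[[`, numeric(1), "reentry_auc")
    met$store_dominant <- vapply(soce, `[[`, logical(1), "store_dominant")
  }
  write_tsv(met, file.path(out_dir, "trace_metrics.tsv"))
  write_config_report(out_dir, list(
    subcommand = "calcium", trace_file = trace_file,
    metadata_file = metadata_file, assay = config$assay,
    baseline_frames = config$baseline_frames,
    responder_threshold_pct = config$responder_threshold_pct,
    viability_rule = config$viability_rule))
  invisible(met)
}

#' Simulate an assay and write the tables the readers consume
#'
#' Closing the loop for end-to-end tests: `kind = "behavior"` writes an
#' event table, `"two_stim"` a two-stimulus table, `"screen"` a screen
#' index table, `"traces"` a wide trace table plus YAML metadata.
#'
#' @param kind One of `"behavior"`, `"two_stim"`, `"screen"`, `"traces"`.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param ... Passed to the corresponding generator.
#' @return Invisibly, the path(s) written.
#' @export
run_simulate <- function(kind = c("behavior", "two_stim", "screen", "traces"),
                         out_dir, seed = 1, ...) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(kind,
    behavior = {
      cohort <- gen_behavior_cohort(seed = seed, ...)
      write_events_table(cohort, file.path(out_dir, "events.csv"))
    },
    two_stim = {
      trials <- gen_two_stim_experiment(seed = seed, ...)
      write_two_stim_table(trials, file.path(out_dir, "two_stim.csv"))
    },
    screen = {
      tab <- gen_screen(seed = seed, ...)
      write_tsv(tab[, c("genotype", "index")], file.path(out_dir, "screen.tsv"))
    },
    traces = {
      args <- list(...)
      n <- if (is.null(args$n_traces)) 5L else args$n_traces
      args$n_traces <- NULL
      seeds <- substream_seeds(seed, n)
      traces <- lapply(seq_len(n), function(i)
        do.call(gen_trace, c(args, list(seed = seeds[i]))))
      tt <- traces[[1]]$times
      wide <- data.frame(time_s = tt)
      for (i in seq_len(n)) wide[[sprintf("roi_%d", i)]] <- traces[[i]]$values
      tab <- file.path(out_dir, "traces.csv")
      utils::write.table(wide, tab, sep = ",", row.names = FALSE, quote = FALSE)
      meta <- list(stim_onset = traces[[1]]$stim_onset,
                   stim_offset = traces[[1]]$stim_offset,
                   signal_kind = traces[[1]]$signal_kind)
      if (length(traces[[1]]$phases))
        meta$phases <- lapply(traces[[1]]$phases, as.numeric)
      yaml::write_yaml(meta, file.path(out_dir, "traces_meta.yaml"))
      c(tab, file.path(out_dir, "traces_meta.yaml"))
    })
  write_config_report(out_dir, list(subcommand = "simulate", kind = kind,
                                    seed = seed))
  invisible(paths)
}
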