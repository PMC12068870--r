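test_that("baseline F0 averages the last frames before stimulus onset", {
  tr <- trace_from_df(function(t) rep(0, length(t)), f0 = 100)
  expect_equal(baseline_f0(tr, assay_config("axon_terminal")), 100)

  # pre-stimulus samples alternate 98/102: mean of the last 10 is 100
  tt <- seq(0, 60, by = 1)
  vals <- rep(c(98, 102), length.out = length(tt))
  tr2 <- fluor_trace(tt, vals, stim_onset = 10.5, stim_offset = 20)
  expect_equal(baseline_f0(tr2, assay_config("axon_terminal")), 100)

  # stimulus at sample 3: too few pre-stimulus samples for any baseline
  tr3 <- fluor_trace(0:20, rep(100, 21), stim_onset = 3, stim_offset = 10)
  expect_error(baseline_f0(tr3, assay_config("axon_terminal")), "need 10")
  # 7 pre-stimulus samples: enough for the 5-frame dissociated-cell rule only
  tr4 <- fluor_trace(0:20, rep(100, 21), stim_onset = 7, stim_offset = 10)
  expect_error(baseline_f0(tr4, assay_config("axon_terminal")), "need 10")
  expect_equal(baseline_f0(tr4, assay_config("dissociated_stretch")), 100)
})

test_that("normalization yields F/F0 with unit baseline", {
  tr <- trace_from_df(function(t) rep(0, length(t)), f0 = 100)
  nr <- normalize_trace(tr, 100)
  expect_true(all(nr$f_over_f0 == 1))
  expect_true(all(nr$df_over_f0 == 0))
  expect_error(normalize_trace(tr, 0), "> 0")

  tr2 <- trace_from_df(function(t) ifelse(t >= 10 & t < 11, 0.5, 0))
  expect_equal(max(normalize_trace(tr2, 100)$f_over_f0), 1.5)
})

test_that("peak ratio takes the earliest maximum in the window", {
  tr <- trace_from_df(function(t) ifelse(t >= 12 & t < 13, 0.42, 0))
  pk <- peak_ratio(tr, 100)
  expect_equal(as.numeric(pk), 1.42)
  expect_equal(attr(pk, "peak_time"), 12)

  flat <- trace_from_df(function(t) rep(0, length(t)))
  expect_equal(as.numeric(peak_ratio(flat, 100)), 1)

  # plateau: earliest peak sample reported
  tr2 <- trace_from_df(function(t) ifelse(t >= 12 & t < 15, 0.3, 0))
  expect_equal(attr(peak_ratio(tr2, 100), "peak_time"), 12)
  expect_error(peak_ratio(tr, 100, window = c(100, 120)), "outside")
})

test_that("trapezoidal AUC matches closed forms and is linear", {
  # dF/F0 == 1 over a 10-s window at 1 Hz -> exactly 10
  tt <- 0:30
  tr <- fluor_trace(tt, ifelse(tt >= 10 & tt <= 20, 200, 100),
                    stim_onset = 10, stim_offset = 20)
  expect_equal(trace_auc(tr, 100), 10)

  flat <- trace_from_df(function(t) rep(0, length(t)))
  expect_equal(trace_auc(flat, 100), 0)

  # exponential transient: analytic integral A*tau*(1 - exp(-T/tau))
  A <- 0.8; tau <- 3; T_ <- 10
  tr2 <- trace_from_df(function(t) ifelse(t >= 10, A * exp(-(t - 10) / tau), 0),
                       fps = 10)
  expect_equal(trace_auc(tr2, 100), A * tau * (1 - exp(-T_ / tau)),
               tolerance = 0.01)

  # linearity: scaling dF/F0 scales the AUC (tolerance 1e-9)
  set.seed(4)
  for (rep in 1:10) {
    df <- runif(101, -0.2, 1)
    tt <- seq(0, 10, by = 0.1)
    base <- fluor_trace(tt, 100 * (1 + df), 2, 8)
    alpha <- runif(1, 0.1, 4)
    scaled <- fluor_trace(tt, 100 * (1 + alpha * df), 2, 8)
    expect_equal(trace_auc(scaled, 100), alpha * trace_auc(base, 100),
                 tolerance = 1e-9)
  }

  expect_error(trace_auc(tr, 100, window = c(10, 10.2)), ">= 2 samples")
})

test_that("trapezoid agrees with a refined-Riemann oracle within 0.5%", {
  # smooth double-exponential transients sampled at >= 10 Hz
  set.seed(14)
  for (rep in 1:5) {
    A <- runif(1, 0.2, 1); r <- runif(1, 0.3, 1); d <- runif(1, 2, 8)
    df_fun <- function(t) ifelse(t >= 10, A * (1 - exp(-(t - 10) / r)) *
                                   exp(-(t - 10) / d), 0)
    tr <- trace_from_df(df_fun, fps = 10, duration = 40, onset = 10, offset = 40)
    # midpoint Riemann sum on a 1000x finer grid
    fine <- seq(10, 40, length.out = 300001)
    mid <- (fine[-1] + fine[-length(fine)]) / 2
    oracle <- sum(df_fun(mid) * diff(fine))
    auc <- trace_auc(tr, 100, window = c(10, 40))
    expect_lt(abs(auc - oracle) / abs(oracle), 0.005)
  }
})

test_that("response duration interpolates threshold crossings", {
  cfg <- assay_config("fillet_poke")   # 10% threshold
  # square pulse 8 s above threshold
  tr <- trace_from_df(function(t) ifelse(t >= 10 & t < 18, 0.5, 0), fps = 10)
  expect_equal(response_duration(tr, 100, cfg), 8, tolerance = 0.11)

  flat <- trace_from_df(function(t) rep(0, length(t)))
  expect_equal(response_duration(flat, 100, cfg), 0)

  # triangular pulse: rises 0 -> 0.4 over 10-15 s, falls back by 20 s.
  # dF crosses 0.1 at 11.25 s and 18.75 s: duration 7.5 s exactly at nodes
  tri <- function(t) ifelse(t >= 10 & t <= 15, 0.08 * (t - 10),
                     ifelse(t > 15 & t <= 20, 0.08 * (20 - t), 0))
  tr2 <- trace_from_df(tri, fps = 2)   # crossings between samples
  expect_equal(response_duration(tr2, 100, cfg), 7.5, tolerance = 1e-9)
})

test_that("responder thresholds are strict and viability-gated", {
  expect_true(classify_responder(1.11, assay_config("fillet_poke")))
  expect_false(classify_responder(1.04, assay_config("dissociated_stretch")))
  # exactly at threshold: non-responder under the strict > rule
  expect_false(classify_responder(1.05, assay_config("dissociated_stretch")))
  expect_false(classify_responder(1.10, assay_config("fillet_poke")))
  expect_true(classify_responder(1.100001, assay_config("fillet_poke")))

  gated <- classify_responder(1.5, assay_config("fillet_poke"), viable = FALSE)
  expect_false(as.logical(gated))
  expect_true(attr(gated, "gated"))
})

test_that("responder classification is monotone in the trace", {
  set.seed(30)
  cfg <- assay_config("dissociated_stretch")
  for (rep in 1:20) {
    df <- runif(61, -0.1, 0.2)
    tt <- seq(0, 30, by = 0.5)
    tr <- fluor_trace(tt, 100 * (1 + df), 10, 20)
    f0 <- baseline_f0(tr, cfg)
    r1 <- classify_responder(peak_ratio(tr, f0), cfg)
    up <- fluor_trace(tt, tr$values + runif(1, 0, 20), 10, 20)
    r2 <- classify_responder(peak_ratio(up, f0), cfg)
    if (isTRUE(as.logical(r1))) expect_true(as.logical(r2))
  }
})

test_that("ionomycin viability gates by percent increase or 10 baseline SDs", {
  iono <- list(ionomycin = c(40, 50))
  mk <- function(peak_df, base_vals = rep(100, 101)) {
    tt <- seq(0, 50, by = 0.5)
    vals <- rep(100, length(tt))
    vals[seq_along(base_vals)] <- base_vals
    vals[tt >= 42 & tt < 44] <- 100 * (1 + peak_df)
    fluor_trace(tt, vals, 10, 20, phases = iono)
  }
  cfg <- assay_config("dissociated_stretch")
  expect_true(viability_gate(mk(0.5), cfg))      # +50%
  expect_false(viability_gate(mk(0.05), cfg))    # +5% excluded

  # Fura rule: baseline SD 0.01 ratio units, peak +0.25 above mean
  set.seed(2)
  tt <- seq(0, 50, by = 0.5)
  vals <- 1 + rnorm(length(tt), 0, 0.01)
  vals[tt >= 42 & tt < 44] <- mean(vals[tt < 10]) + 0.25
  trf <- fluor_trace(tt, vals, 10, 20, phases = iono)
  cfg_f <- assay_config("hacat_fura")
  pre <- which(trf$times < 10)
  base <- trf$values[utils::tail(pre, cfg_f$baseline_frames)]
  oracle <- max(vals[tt >= 40 & tt <= 50]) > mean(base) + 10 * sd(base)
  expect_identical(viability_gate(trf, cfg_f), oracle)
  expect_true(viability_gate(trf, cfg_f))

  no_phase <- trace_from_df(function(t) rep(0.5, length(t)))
  expect_error(viability_gate(no_phase, cfg), "ionomycin")
})

test_that("SOCE metrics integrate the store and re-entry phases separately", {
  phases <- list(zero_ca = c(10, 30), ca_readdition = c(30, 50))
  # triangular bumps (vertices on the sample grid, so the trapezoid rule is
  # exact): store area 3.0 over 14-20 s, re-entry area 1.0 over 34-38 s
  tri <- function(t, a, p, b, h)
    ifelse(t >= a & t <= p, h * (t - a) / (p - a),
    ifelse(t > p & t <= b, h * (b - t) / (b - p), 0))
  df_fun <- function(t) tri(t, 14, 17, 20, 1) + tri(t, 34, 36, 38, 0.5)
  tt <- (0:600) / 10   # exact decimal grid so bump vertices are nodes
  mk_tr <- function(df_fun) fluor_trace(tt, 100 * (1 + df_fun(tt)), 10, 30,
                                        phases = phases)
  tr <- mk_tr(df_fun)
  m <- soce_phase_metrics(tr, f0 = 100)
  expect_equal(m$store_auc, 3, tolerance = 1e-9)
  expect_equal(m$reentry_auc, 1, tolerance = 1e-9)
  expect_true(m$store_dominant)

  # equal areas: strictly-greater rule makes the cell NOT store-dominant
  df_eq <- function(t) tri(t, 14, 17, 20, 1) + tri(t, 34, 37, 40, 1)
  m2 <- soce_phase_metrics(mk_tr(df_eq), f0 = 100)
  expect_equal(m2$store_auc, m2$reentry_auc)
  expect_false(m2$store_dominant)

  # windowing correctness: signal outside both phases does not leak in
  df_noise <- function(t) df_fun(t) + ifelse(t > 52, 5, 0)
  m3 <- soce_phase_metrics(mk_tr(df_noise), f0 = 100)
  expect_equal(m3$store_auc, m$store_auc)
  expect_equal(m3$reentry_auc, m$reentry_auc)

  no_phase <- trace_from_df(df_fun, fps = 10, duration = 60)
  expect_error(soce_phase_metrics(no_phase, f0 = 100), "zero_ca")
  expect_error(fluor_trace(0:10, rep(1, 11), 1, 2,
                           phases = list(zero_ca = c(1, 5),
                                         ca_readdition = c(4, 8))),
               "overlap")
})

test_that("recruitment curves derive thresholds, cumulative and new fractions", {
  # 100 cells: 18 respond from 0.5%, 10 more first respond at 1%
  resp <- matrix(FALSE, 100, 4)
  resp[1:18, ] <- TRUE
  resp[19:28, 2:4] <- TRUE
  rc <- recruitment_curve(stretch_series(c(0.5, 1, 2.5, 5), resp))
  expect_equal(rc$cumulative, c(0.18, 0.28, 0.28, 0.28))
  expect_equal(rc$newly_recruited, c(0.18, 0.10, 0, 0))
  expect_equal(rc$overall_fraction, 0.28)
  expect_equal(as.integer(table(rc$thresholds)), c(18L, 10L))

  # threshold histogram sums to the overall responsive fraction
  expect_equal(length(rc$thresholds) / rc$n_cells, rc$overall_fraction)

  none <- recruitment_curve(stretch_series(c(1, 2), matrix(FALSE, 5, 2)))
  expect_equal(none$cumulative, c(0, 0))
  expect_length(none$thresholds, 0)

  all1 <- recruitment_curve(stretch_series(c(1, 2), matrix(TRUE, 5, 2)))
  expect_equal(all1$cumulative, c(1, 1))
  expect_equal(all1$newly_recruited, c(1, 0))

  expect_error(stretch_series(c(2, 1), matrix(TRUE, 2, 2)), "increasing")
})

test_that("cohort fractions count predicate matches", {
  mets <- lapply(1:24, function(i) list(responder = i <= 12))
  cf <- cohort_fraction(mets, function(m) m$responder)
  expect_equal(cf$fraction, 0.5)

  # overlap predicate (responds to A AND B) matches a hand count
  cells <- lapply(1:20, function(i) list(a = i <= 8, b = i %in% 5:14))
  both <- cohort_fraction(cells, function(c) c$a && c$b)
  expect_equal(both$numerator, 4L)   # cells 5..8

  expect_equal(cohort_fraction(rep(FALSE, 6))$fraction, 0)
  expect_error(cohort_fraction(list()), "empty")
})

test_that("per-trace metric summaries assemble consistently", {
  tr <- trace_from_df(function(t) ifelse(t >= 10, 0.4 * exp(-(t - 10) / 5), 0),
                      fps = 10, duration = 60)
  m <- trace_metrics(tr, assay_config("fillet_poke"))
  expect_equal(m$f0, 100)
  expect_equal(m$fmax_over_f0, 1.4)
  expect_equal(m$pct_increase, 40)
  expect_true(m$responder)
  expect_true(m$viable)
  expect_equal(m$decay$tau, 5, tolerance = 1e-4)

  tab <- cohort_trace_metrics(list(roi_1 = tr, roi_2 = tr))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$roi, c("roi_1", "roi_2"))
})
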