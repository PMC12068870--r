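test_that("responded uses half-open windows with positive-overlap semantics", {
  tr <- make_trial("a", list(c("roll", 10, 12)))
  expect_true(responded(tr, "roll", c(9, 19)))
  tr2 <- make_trial("b", list(c("roll", 0, 8)))
  expect_false(responded(tr2, "roll", c(9, 19)))
  # 0.5 s overlap at the window edge counts
  tr3 <- make_trial("c", list(c("roll", 8, 9.5)))
  expect_true(responded(tr3, "roll", c(9, 19)))
  # event ending exactly at window start: zero overlap
  tr4 <- make_trial("d", list(c("roll", 8, 9)))
  expect_false(responded(tr4, "roll", c(9, 19)))
  # zero-duration event inside [a, b); boundary b excluded
  tr5 <- make_trial("e", list(c("roll", 9, 9)))
  expect_true(responded(tr5, "roll", c(9, 19)))
  expect_false(responded(tr5, "roll", c(5, 9)))
  # labels matched case-insensitively after trimming
  tr6 <- make_trial("f", list(c(" Roll ", 10, 12)))
  expect_true(responded(tr6, "roll", c(9, 19)))
  # strict mode rejects unknown labels; lenient returns FALSE
  expect_error(responded(tr, "hunch", c(9, 19), strict = TRUE), "unknown behavior")
  expect_false(responded(tr, "hunch", c(9, 19)))
})

test_that("response probability counts responders over all trials", {
  expect_equal(response_probability(counted_cohort(50, 50), "roll", c(10, 20))$fraction, 1)
  expect_equal(response_probability(counted_cohort(0, 50), "roll", c(10, 20))$fraction, 0)
  rp <- response_probability(counted_cohort(36, 50), "roll", c(10, 20))
  expect_equal(rp$numerator, 36L)
  expect_equal(rp$fraction, 0.72)
  expect_error(response_probability(behavior_cohort(list()), "roll", c(0, 1)),
               "empty")
})

test_that("response probability is monotone under window enlargement", {
  set.seed(11)
  for (rep in 1:20) {
    ch <- random_cohort(10)
    w <- sort(runif(2, 0, 25))
    if (diff(w) < 0.1) next
    p_small <- response_probability(ch, "roll", w)$fraction
    p_big <- response_probability(ch, "roll", c(w[1] - 1, w[2] + 2))$fraction
    expect_gte(p_big, p_small)
  }
})

test_that("binned fractions match the per-bin overlap oracle", {
  # continuous roll through the 10-s stimulus: fraction 1 in all stim bins
  ch <- make_cohort(make_trial("a", list(c("roll", 10, 20))))
  eth <- bin_fractions(ch, "roll", span = c(10, 20))
  expect_equal(unname(eth$fractions["roll", ]), rep(1, 10))

  # event spanning a bin edge lands in both bins
  ch2 <- make_cohort(make_trial("b", list(c("roll", 10.5, 11.5))))
  eth2 <- bin_fractions(ch2, "roll", span = c(10, 13))
  expect_equal(unname(eth2$fractions["roll", ]), c(1, 1, 0))

  # no events: all-zero matrix
  eth3 <- bin_fractions(make_cohort(make_trial("c")), "roll", span = c(0, 5))
  expect_true(all(eth3$fractions == 0))
  expect_error(bin_fractions(ch, "roll", span = c(0, 5), bin_width = 0), "> 0")

  # oracle equivalence on random cohorts
  set.seed(7)
  for (rep in 1:15) {
    ch <- random_cohort(sample(1:20, 1))
    eth <- bin_fractions(ch, c("roll", "freeze"), span = c(0, 30))
    for (b in c("roll", "freeze")) {
      for (k in seq_len(ncol(eth$fractions))) {
        w1 <- eth$bin_edges[k]; w2 <- eth$bin_edges[k + 1]
        oracle <- mean(vapply(ch$trials, oracle_overlaps, logical(1),
                              behavior = b, w1 = w1, w2 = w2))
        expect_equal(unname(eth$fractions[b, k]), oracle)
      }
    }
  }
})

test_that("latency is to the first event initiated at or after t0, responders only", {
  ch <- make_cohort(
    make_trial("a", list(c("roll", 12.3, 14))),
    make_trial("b", list()),                        # no rolls: excluded
    make_trial("c", list(c("roll", 11, 12), c("roll", 15, 16))),
    make_trial("d", list(c("roll", 5, 15))))        # started before t0: excluded
  lat <- latency_to_first(ch, "roll", t0 = 10)
  expect_equal(sort(names(lat)), c("a", "c"))
  expect_equal(lat[["a"]], 2.3)
  expect_equal(lat[["c"]], 1)  # earliest of the two rolls
})

test_that("bout durations sum clipped overlaps for displayers only", {
  ch <- make_cohort(
    make_trial("a", list(c("roll", 10, 14))),
    make_trial("b", list(c("roll", 8, 12))),           # clipped to 2 s
    make_trial("c", list(c("roll", 11, 12), c("roll", 13, 15.5))),
    make_trial("d", list(c("freeze", 12, 14))))        # not displaying roll
  d <- bout_durations(ch, "roll", c(10, 20))
  expect_equal(sort(names(d)), c("a", "b", "c"))
  expect_equal(d[["a"]], 4)
  expect_equal(d[["b"]], 2)
  expect_equal(d[["c"]], 3.5)

  # property: total bout overlap never exceeds window length
  set.seed(5)
  for (rep in 1:20) {
    ch <- random_cohort(8)
    d <- bout_durations(ch, "roll", c(5, 15))
    if (!is.null(d)) expect_true(all(d <= 10 + 1e-12))
  }
})

test_that("post-stimulus persistence uses all trials as denominator", {
  ch <- make_cohort(
    make_trial("a", list(c("freeze", 20, 25))),   # after offset at 20 s
    make_trial("b", list(c("freeze", 12, 18))),   # only during stimulus
    make_trial("c", list()))
  pe <- post_stimulus_persistence(ch, "freeze")
  expect_equal(pe$numerator, 1L)
  expect_equal(pe$denominator, 3L)   # all trials, not displayers
})

test_that("cumulative response curve matches the sort-and-count oracle", {
  ch <- make_cohort(
    make_trial("a", list(c("roll", 11, 12))),
    make_trial("b", list(c("roll", 11, 12))),
    make_trial("c", list(c("roll", 13, 14))),
    make_trial("d", list()))
  cc <- cumulative_response_curve(ch, "roll", t0 = 10, t_end = 20,
                                  resolution = 0.5)
  at <- function(t) cc$fraction[match(t, cc$time)]
  expect_equal(at(0.5), 0)
  expect_equal(at(1), 0.5)
  expect_equal(at(2.5), 0.5)
  expect_equal(at(3), 0.75)
  expect_equal(cc$fraction[nrow(cc)], 0.75)
  expect_true(all(diff(cc$fraction) >= 0))
  # terminal value equals response_probability exactly
  expect_identical(cc$fraction[nrow(cc)],
                   response_probability(ch, "roll", c(10, 20))$fraction)
  # no responders: identically zero
  cc0 <- cumulative_response_curve(make_cohort(make_trial("x")), "roll", 10, 20)
  expect_true(all(cc0$fraction == 0))
})

test_that("event counts tally overlapping events", {
  tr <- make_trial("a", lapply(seq(10, 18, by = 2), function(s)
    c("roll", s, s + 1)))
  expect_equal(event_count(tr, "roll", c(10, 20)), 5L)
  expect_equal(event_count(tr, "roll", c(30, 40)), 0L)
  # cohort mean-of-counts summary over responders
  ch <- make_cohort(tr, make_trial("b", list(c("roll", 10, 11))))
  counts <- vapply(ch$trials, event_count, integer(1),
                   behavior = "roll", window = c(10, 20))
  expect_equal(mean(counts), 3)
})
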