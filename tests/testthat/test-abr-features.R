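onset <- 2001L

test_that("average_epochs matches a naive loop and handles degenerate sets", {
  set.seed(11)
  m <- matrix(rnorm(10 * 100), nrow = 10)
  expect_equal(average_epochs(m), oracle_col_means(m), tolerance = 1e-12)
  # identical traces average to themselves; +v/-v averages to zero
  t1 <- rnorm(50)
  expect_equal(average_epochs(rbind(t1, t1, t1)), t1)
  expect_equal(average_epochs(rbind(t1, -t1)), rep(0, 50))
  expect_error(average_epochs(matrix(numeric(0), nrow = 0, ncol = 5)),
               "at least one")
})

test_that("baseline_stats uses the 200-100 ms pre-onset window, population SD", {
  tr <- flat_trace(value = 3.5)
  bs <- baseline_stats(tr, onset)
  expect_equal(bs$mean, 3.5)
  expect_equal(bs$sd, 0)
  # alternating +/-1 in the window: mean 0, population SD exactly 1
  tr <- flat_trace()
  tr[1:1000] <- rep(c(1, -1), 500)
  bs <- baseline_stats(tr, onset)
  expect_equal(bs$mean, 0)
  expect_equal(bs$sd, 1)
  # random trace agrees with a two-pass oracle on the same window
  set.seed(12)
  tr <- rnorm(2150)
  bs <- baseline_stats(tr, onset)
  or <- oracle_mean_sd_pop(tr[1:1000])
  expect_equal(bs$mean, or$mean, tolerance = 1e-12)
  expect_equal(bs$sd, or$sd, tolerance = 1e-12)
  expect_error(baseline_stats(rnorm(100), onset_sample = 50L), "outside")
})

test_that("evoked_amplitude is the max absolute deviation in 1-5 ms", {
  tr <- flat_trace()
  bs <- baseline_stats(tr, onset)
  expect_equal(evoked_amplitude(tr, onset, bs), 0)
  # a single +0.5 mV spike at 3 ms on a zero baseline
  tr[onset + 30] <- 0.5
  expect_equal(evoked_amplitude(tr, onset, baseline_stats(tr, onset)), 0.5)
  set.seed(13)
  tr <- rnorm(2150, sd = 0.1)
  bs <- baseline_stats(tr, onset)
  win <- tr[(onset + 10):(onset + 49)]
  expect_equal(evoked_amplitude(tr, onset, bs),
               oracle_window_max_abs_dev(win, bs$mean), tolerance = 1e-12)
})

test_that("compute_rms matches analytic values and a naive loop", {
  tr <- flat_trace(value = 2.5)
  expect_equal(compute_rms(tr, onset), 2.5)
  # degenerate two-sample window {3, -4} -> sqrt(12.5)
  tr2 <- rep(0, 40)
  tr2[31:32] <- c(3, -4)
  expect_equal(compute_rms(tr2, onset_sample = 21L, sampling_rate = 10000,
                           window_ms = c(1, 1.2)),
               sqrt(12.5), tolerance = 1e-12)
  set.seed(14)
  tr <- rnorm(2150)
  expect_equal(compute_rms(tr, onset),
               oracle_rms(tr[(onset + 10):(onset + 49)]), tolerance = 1e-12)
})

test_that("detect_waves recovers constructed pulses and is linear", {
  # four disjoint triangular pulses at 1.5 / 2.6 / 3.6 / 5.0 ms
  lats <- c(1.5, 2.6, 3.6, 5.0)
  amps <- c(0.5, 0.3, 0.9, 0.6)
  tr <- flat_trace()
  for (i in 1:4) {
    pk <- onset + round(lats[i] * 10)
    tr[pk] <- amps[i] * 2 / 3
    tr[pk + 3] <- -amps[i] / 3
  }
  wf <- detect_waves(tr, onset)
  expect_equal(wf$latency_ms, lats, tolerance = 0.2)
  expect_equal(wf$peak_to_peak_mv, amps, tolerance = 0.05 * max(amps))
  # doubling the trace doubles amplitudes, leaves latencies unchanged
  wf2 <- detect_waves(2 * tr, onset)
  expect_equal(wf2$peak_to_peak_mv, 2 * wf$peak_to_peak_mv)
  expect_equal(wf2$latency_ms, wf$latency_ms)
  # flat trace: all waves missing, with a warning
  expect_warning(wf0 <- detect_waves(flat_trace(), onset), "no ABR waves")
  expect_true(all(is.na(wf0$peak_to_peak_mv)))
})

test_that("detected wave latencies are reported in increasing order", {
  ep <- simulate_abr_epochs(abr_truth(threshold_db = 35),
                            stimulus_spec("tone", frequency_khz = 4,
                                          level_db = 70),
                            n_reps = 60, seed = 21)
  wf <- detect_waves(average_epochs(ep), ep$onset_sample)
  lat <- wf$latency_ms[!is.na(wf$latency_ms)]
  expect_true(all(diff(lat) > 0))
})
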