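truth_40 <- abr_truth(threshold_db = 40)
tone70 <- stimulus_spec("tone", frequency_khz = 2, level_db = 70)

test_that("epoch sets have the requested size, geometry and metadata", {
  ep <- simulate_abr_epochs(truth_40, tone70, n_reps = 120, seed = 1)
  expect_equal(nrow(ep$traces), 120)
  expect_equal(ep$sampling_rate, 10000)
  # a full 200 ms baseline precedes the onset
  expect_gte(ep$onset_sample - 1, 2000)
  ep5 <- simulate_abr_epochs(truth_40, tone70, n_reps = 5, seed = 1)
  expect_equal(nrow(ep5$traces), 5)
})

test_that("stimulus grids are enforced", {
  expect_error(stimulus_spec("tone", frequency_khz = 2, level_db = 72),
               "grid")
  expect_error(stimulus_spec("tone", frequency_khz = 3, level_db = 70),
               "half-octave")
  expect_error(simulate_abr_epochs(truth_40, tone70, n_reps = 0), "n_reps")
  expect_silent(stimulus_spec("click", level_db = 70))
})

test_that("below threshold with zero noise every trace is exactly zero", {
  quiet <- abr_truth(threshold_db = 40, noise_sd_mv = 0)
  sub <- stimulus_spec("tone", frequency_khz = 2, level_db = 30)
  ep <- simulate_abr_epochs(quiet, sub, n_reps = 10, seed = 3)
  expect_true(all(ep$traces == 0))
  # and above threshold the evoked component appears only after onset
  ep70 <- simulate_abr_epochs(quiet, tone70, n_reps = 2, seed = 3)
  expect_true(all(ep70$traces[, 1:(ep70$onset_sample - 1)] == 0))
  expect_gt(max(abs(ep70$traces)), 0)
})

test_that("identical seeds give bit-identical epoch sets", {
  a <- simulate_abr_epochs(truth_40, tone70, n_reps = 8, seed = 42)
  b <- simulate_abr_epochs(truth_40, tone70, n_reps = 8, seed = 42)
  expect_identical(a$traces, b$traces)
  c <- simulate_abr_epochs(truth_40, tone70, n_reps = 8, seed = 43)
  expect_false(identical(a$traces, c$traces))
})

test_that("collapsed simulation matches the epoch-average law", {
  # one collapsed trace is signal + noise at sd/sqrt(n); its variance over
  # the baseline window should match that scaling
  quiet <- abr_truth(threshold_db = 40, noise_sd_mv = 0)
  col <- simulate_abr_epochs(quiet, tone70, n_reps = 120, seed = 9,
                             collapse = TRUE)
  full <- simulate_abr_epochs(quiet, tone70, n_reps = 1, seed = 9)
  # zero noise: collapsed trace equals the pure signal (= any single epoch)
  expect_equal(as.numeric(col$traces), as.numeric(full$traces))
  noisy <- abr_truth(threshold_db = 40, noise_sd_mv = 0.15)
  cols <- vapply(1:40, function(s) {
    tr <- simulate_abr_epochs(noisy, tone70, n_reps = 100, seed = s,
                              collapse = TRUE)$traces
    stats::sd(tr[1, 1:2000])
  }, numeric(1))
  expect_equal(mean(cols), 0.15 / sqrt(100), tolerance = 0.1)
})

test_that("truth model respects wave ordering and growth invariants", {
  tr <- abr_truth(threshold_db = 40)
  for (L in c(45, 60, 75, 90)) {
    lat <- tr$latency(L)
    expect_true(all(diff(lat) > 0))          # latencies increase with wave
    expect_true(all(tr$amplitude(L) >= 0))
  }
  # latency non-increasing in level, amplitude non-decreasing above threshold
  expect_true(all(tr$latency(50) >= tr$latency(90)))
  expect_true(all(tr$amplitude(60) <= tr$amplitude(90)))
  expect_equal(tr$amplitude(40), rep(0, 4))  # zero at threshold and below
  expect_error(abr_truth(40, wave_lat70_ms = c(2, 1.5, 3, 4)))
})
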