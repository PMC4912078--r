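# Helper: a level series of pre-averaged traces from a truth model,
# optionally scaled, with per-level seeds.
make_series <- function(truth, levels = abr_level_grid(), scale = 1,
                        seed0 = 500, freq = 2, n_reps = 120) {
  series <- lapply(levels, function(L) {
    ep <- simulate_abr_epochs(truth,
                              stimulus_spec("tone", frequency_khz = freq,
                                            level_db = L),
                              n_reps = n_reps, seed = seed0 + L,
                              collapse = TRUE)
    tr <- average_epochs(ep)
    sig <- simulate_abr_epochs(abr_truth(truth$threshold_db,
                                         truth$wave_amp_mv,
                                         truth$wave_lat70_ms,
                                         noise_sd_mv = 0),
                               stimulus_spec("tone", frequency_khz = freq,
                                             level_db = L),
                               n_reps = 1, seed = 1)
    # scale only the evoked component, leaving the noise untouched
    tr <- tr + (scale - 1) * as.numeric(sig$traces)
    attr(tr, "onset_sample") <- ep$onset_sample
    attr(tr, "sampling_rate") <- ep$sampling_rate
    tr
  })
  names(series) <- levels
  series
}

test_that("noiseless series yield the exact threshold boundary cases", {
  quiet <- abr_truth(threshold_db = 40, noise_sd_mv = 0)
  series <- make_series(quiet)
  # responses exist only above 40 dB; first qualifying grid level is 45
  expect_equal(detect_threshold(series), 45)
  # responses at every level including 0 dB -> threshold 0
  all_resp <- abr_truth(threshold_db = -10, noise_sd_mv = 0)
  expect_equal(detect_threshold(make_series(all_resp)), 0)
  # pure silence at all levels -> missing
  silent <- abr_truth(threshold_db = 95, noise_sd_mv = 0)
  expect_true(is.na(detect_threshold(make_series(silent))))
})

test_that("pure-noise series report a missing threshold", {
  deaf <- abr_truth(threshold_db = 95, noise_sd_mv = 0.15)
  expect_true(is.na(detect_threshold(make_series(deaf, seed0 = 700))))
})

test_that("detect_threshold rejects malformed input", {
  expect_error(detect_threshold(list()), "empty")
  tr <- flat_trace()
  expect_error(detect_threshold(setNames(list(tr), "42")), "grid")
})

test_that("scaling evoked components up never raises the threshold", {
  truth <- abr_truth(threshold_db = 45, noise_sd_mv = 0.15)
  for (s in c(801, 802, 803)) {
    base <- detect_threshold(make_series(truth, seed0 = s))
    boosted <- detect_threshold(make_series(truth, seed0 = s, scale = 2.5))
    if (!is.na(base)) {
      expect_false(is.na(boosted))
      expect_lte(boosted, base)
    }
  }
})

test_that("detected thresholds stay on the 0-90/5 grid or missing", {
  for (thr in c(25, 50, 70)) {
    truth <- abr_truth(threshold_db = thr, noise_sd_mv = 0.15)
    est <- detect_threshold(make_series(truth, seed0 = 900 + thr))
    expect_true(is.na(est) || est %in% abr_level_grid())
  }
})

test_that("audiograms assemble, preserve missings, and difference correctly", {
  ag <- build_audiogram(c(`1` = 40, `4` = NA, `2` = 45))
  expect_s3_class(ag, "audiogram")
  expect_equal(ag$frequency_khz, c(1, 2, 4))       # ordered by frequency
  expect_equal(ag$threshold_db, c(40, 45, NA))
  expect_equal(nrow(build_audiogram(c(`8` = 55))), 1)
  all_na <- build_audiogram(c(`1` = NA, `2` = NA))
  expect_true(all(is.na(all_na$threshold_db)))

  pre <- build_audiogram(c(`1` = 40, `2` = 45, `4` = 50))
  expect_equal(threshold_shift(pre, pre)$mean_shift_db, 0)
  post <- pre; post$threshold_db <- post$threshold_db + 15
  sh <- threshold_shift(pre, post)
  expect_equal(sh$mean_shift_db, 15)
  expect_true(all(sh$per_frequency$shift_db == 15))
  # no overlap -> error
  other <- build_audiogram(c(`8` = 60))
  expect_error(threshold_shift(pre, other), "common")
})

test_that("a flat 50 dB ear is recovered within one grid step", {
  truth <- abr_truth(threshold_db = 50, noise_sd_mv = 0.15)
  ths <- vapply(c(1, 2, 4), function(f) {
    detect_threshold(make_series(truth, seed0 = 1000 + f * 7, freq = f))
  }, numeric(1))
  ag <- build_audiogram(setNames(ths, c(1, 2, 4)))
  expect_true(all(abs(ag$threshold_db - 50) <= 5))
})
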