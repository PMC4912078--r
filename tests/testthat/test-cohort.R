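cfg_small <- cohort_config(n_treated = 2, n_vehicle = 2,
                           abr_frequencies_khz = c(1, 4), seed = 7)

test_that("the default design has 11 treated and 9 vehicle animals", {
  coh <- make_cohort(cohort_config(seed = 1))
  expect_equal(nrow(coh$animals), 20)
  expect_equal(sum(coh$animals$group == "G"), 11)
  expect_equal(sum(coh$animals$group == "V"), 9)
})

test_that("cohort generation is deterministic and seed-sensitive", {
  a <- make_cohort(cfg_small)
  b <- make_cohort(cfg_small)
  expect_identical(a$abr, b$abr)
  expect_identical(a$ppi, b$ppi)
  ep_a <- cohort_abr_epochs(a, "A01", "pre_trauma", "left", 1, 50, n_reps = 4)
  ep_b <- cohort_abr_epochs(b, "A01", "pre_trauma", "left", 1, 50, n_reps = 4)
  expect_identical(ep_a$traces, ep_b$traces)
  ss_a <- cohort_startle_session(a, "A02", "week1")
  ss_b <- cohort_startle_session(b, "A02", "week1")
  expect_identical(ss_a$traces, ss_b$traces)
  c2 <- make_cohort(cohort_config(n_treated = 2, n_vehicle = 2,
                                  abr_frequencies_khz = c(1, 4), seed = 8))
  expect_false(identical(a$ppi, c2$ppi))
})

test_that("zero trauma leaves post-trauma audiograms untouched", {
  cfg0 <- cohort_config(n_treated = 1, n_vehicle = 1, trauma_shift_db = 0,
                        abr_frequencies_khz = c(1, 4), seed = 9)
  coh <- make_cohort(cfg0)
  for (f in c(1, 4)) {
    expect_equal(true_threshold(coh, "A01", "left", f, "post_trauma"),
                 true_threshold(coh, "A01", "left", f, "pre_trauma"))
  }
})

test_that("the trauma shift is parallel and recovers per group profile", {
  coh <- make_cohort(cfg_small)
  for (a in coh$animals$animal) {
    shifts <- vapply(c(1, 4), function(f) {
      true_threshold(coh, a, "left", f, "post_trauma") -
        true_threshold(coh, a, "left", f, "pre_trauma")
    }, numeric(1))
    # frequency-independent (parallel) shift within animal
    expect_equal(shifts[1], shifts[2])
    expect_gte(shifts[1], 0)
    grp <- coh$animals$group[coh$animals$animal == a]
    wk3 <- true_threshold(coh, a, "left", 1, "week3") -
      true_threshold(coh, a, "left", 1, "pre_trauma")
    if (grp == "G") {
      expect_equal(wk3, 0)                       # full treated recovery
    } else {
      expect_equal(wk3, shifts[1])               # vehicle stays shifted
    }
  }
})

test_that("tinnitus-positive animals have 1-3 affected frequencies", {
  coh <- make_cohort(cohort_config(seed = 11))
  for (i in seq_len(nrow(coh$animals))) {
    k <- length(coh$animals$affected_freqs_khz[[i]])
    if (coh$animals$tinnitus_positive[i]) {
      expect_gte(k, 1)
      expect_lte(k, 3)
      expect_true(all(coh$animals$affected_freqs_khz[[i]] %in%
                        startle_frequencies()))
    } else {
      expect_equal(k, 0)
    }
  }
})

test_that("tinnitus resolves under treatment and reappears at week 4", {
  coh <- make_cohort(cfg_small)
  expect_equal(noisetrauma:::cohort_tinnitus_fraction(coh, "G", "week3"), 0)
  expect_equal(noisetrauma:::cohort_tinnitus_fraction(coh, "G", "week4"), 1)
  expect_equal(noisetrauma:::cohort_tinnitus_fraction(coh, "V", "week3"), 1)
  expect_equal(noisetrauma:::cohort_tinnitus_fraction(coh, "V", "pre_trauma"), 0)
})

test_that("config invariants are validated", {
  expect_error(cohort_config(n_treated = 0, n_vehicle = 0))
  expect_error(cohort_config(recovery_fraction_treated = 1.5))
  expect_error(cohort_config(max_tinnitus_freqs = 6))
  expect_error(cohort_config(levels_db = c(0, 7)), "grid")
  expect_error(cohort_config(abr_frequencies_khz = 3), "half-octave")
})
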