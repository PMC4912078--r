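#' Generate a two-group noise-trauma cohort with known ground truth
#'
#' Realizes a [cohort_config()] into a full experiment dataset: per-animal
#' group assignment, tinnitus status (which animals develop a percept and at
#' which 1 to `max_tinnitus_freqs` startle frequencies), per-ear/frequency
#' true ABR thresholds and wave parameters, and baseline gap-PPI. The trauma
#' is applied between `pre_trauma` and `post_trauma` as a
#' frequency-independent ("parallel") threshold shift; treated-group
#' thresholds and tinnitus recover across weeks 1-3 according to the config,
#' the vehicle group's do not, and tinnitus reappears at week 4 in treated
#' animals when configured.
#'
#' Traces are not materialized here: the cohort is a lazy handle, and
#' [cohort_abr_epochs()] / [cohort_startle_session()] synthesize any
#' requested condition deterministically from per-condition child seeds.
#' Ground truth is stored for bookkeeping and validation only; analysis
#' functions never read it.
#'
#' @param config A [cohort_config()].
#' @return A `noise_cohort` object with elements `config`, `animals` (design
#'   data frame), `abr` (per animal x ear x frequency truth), and
#'   `wave_params` / `ppi` per-animal truth tables.
#' @export
make_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  n <- config$n_treated + config$n_vehicle
  ids <- sprintf("A%02d", seq_len(n))
  groups <- c(rep("G", config$n_treated), rep("V", config$n_vehicle))

  set.seed(child_seed(config$seed, "design"))
  tinnitus_positive <- runif(n) < config$tinnitus_prevalence
  # per-animal realized parallel trauma shift, on the 5 dB grid
  trauma_shift <- pmax(0, 5 * round(rnorm(n, config$trauma_shift_db,
                                          config$trauma_shift_sd_db) / 5))
  if (config$trauma_shift_db == 0) trauma_shift[] <- 0
  affected <- lapply(seq_len(n), function(i) {
    if (!tinnitus_positive[i]) return(numeric(0))
    k <- sample(seq_len(config$max_tinnitus_freqs), 1)
    sort(sample(startle_frequencies(), k))
  })
  animals <- data.frame(animal = ids, group = groups,
                        tinnitus_positive = tinnitus_positive,
                        trauma_shift_db = trauma_shift)
  animals$affected_freqs_khz <- I(affected)

  # Pre-trauma true thresholds per animal x ear x frequency, on the 5 dB grid
  ears <- c("left", "right")
  abr_grid <- expand.grid(animal = ids, ear = ears,
                          frequency_khz = config$abr_frequencies_khz,
                          stringsAsFactors = FALSE)
  set.seed(child_seed(config$seed, "thresholds"))
  thr <- rnorm(nrow(abr_grid), config$threshold_mean_db, config$threshold_sd_db)
  abr_grid$base_threshold_db <- pmin(65, pmax(20, 5 * round(thr / 5)))

  # Per-animal wave parameters (latency and amplitude variability)
  set.seed(child_seed(config$seed, "waves"))
  wave_params <- lapply(seq_len(n), function(i) {
    l70 <- c(1.6, 2.7, 3.7, 5.2) + rnorm(4, 0, 0.08)
    l70 <- sort(l70)
    amp <- c(0.6, 0.45, 0.9, 0.7) * rlnorm(4, 0, 0.15)
    list(wave_lat70_ms = l70, wave_amp_mv = amp)
  })
  names(wave_params) <- ids

  # Baseline gap-PPI per animal x startle frequency
  set.seed(child_seed(config$seed, "ppi"))
  ppi <- matrix(pmin(85, pmax(40, rnorm(n * 5, config$baseline_ppi_mean,
                                        config$baseline_ppi_sd))),
                nrow = n, dimnames = list(ids, startle_frequencies()))

  structure(list(config = config, animals = animals, abr = abr_grid,
                 wave_params = wave_params, ppi = ppi),
            class = "noise_cohort")
}

#' @export
print.noise_cohort <- function(x, ...) {
  cat(sprintf("<noise_cohort> %d animals (%d G + %d V), %d tinnitus-positive\n",
              nrow(x$animals), sum(x$animals$group == "G"),
              sum(x$animals$group == "V"), sum(x$animals$tinnitus_positive)))
  invisible(x)
}

cohort_shift_fraction <- function(cohort, group, session) {
  rf <- if (group == "G") cohort$config$recovery_fraction_treated else
    cohort$config$recovery_fraction_vehicle
  unname(shift_profile(rf)[session])
}

cohort_tinnitus_fraction <- function(cohort, group, session) {
  rf <- if (group == "G") cohort$config$recovery_fraction_treated else
    cohort$config$recovery_fraction_vehicle
  unname(tinnitus_profile(rf, group == "G" &&
                            cohort$config$tinnitus_reappears_week4)[session])
}

#' True ABR threshold for one cohort condition
#'
#' Ground-truth bookkeeping: the pre-trauma base threshold plus the trauma
#' shift still present at the given session. Not used by any analysis code.
#'
#' @param cohort A [make_cohort()] result.
#' @param animal,ear,frequency_khz,session Condition selectors.
#' @return Threshold in dB SPL.
#' @export
true_threshold <- function(cohort, animal, ear, frequency_khz, session) {
  row <- cohort$abr[cohort$abr$animal == animal & cohort$abr$ear == ear &
                      abs(cohort$abr$frequency_khz - frequency_khz) < 1e-6, ]
  if (nrow(row) != 1) stop("no such cohort condition")
  i <- match(animal, cohort$animals$animal)
  grp <- cohort$animals$group[i]
  row$base_threshold_db +
    cohort$animals$trauma_shift_db[i] *
      cohort_shift_fraction(cohort, grp, session)
}

#' Simulate the ABR epoch set of one cohort condition
#'
#' @inheritParams true_threshold
#' @param level_db Stimulus level on the 0-90/5 grid.
#' @param n_reps Repetitions; defaults to the cohort config.
#' @param collapse Return the epoch average as a single trace (see
#'   [simulate_abr_epochs()]).
#' @return An `abr_epochs` object (deterministic per condition).
#' @export
cohort_abr_epochs <- function(cohort, animal, session, ear, frequency_khz,
                              level_db, n_reps = cohort$config$n_reps,
                              collapse = FALSE) {
  thr <- true_threshold(cohort, animal, ear, frequency_khz, session)
  wp <- cohort$wave_params[[animal]]
  truth <- abr_truth(threshold_db = thr,
                     wave_amp_mv = wp$wave_amp_mv,
                     wave_lat70_ms = wp$wave_lat70_ms,
                     noise_sd_mv = cohort$config$noise_sd_mv)
  stim <- stimulus_spec("tone", frequency_khz = frequency_khz,
                        level_db = level_db)
  seed <- child_seed(cohort$config$seed, "abr", animal, session, ear,
                     frequency_khz, level_db)
  simulate_abr_epochs(truth, stim, n_reps = n_reps, seed = seed,
                      animal_id = animal, ear = ear, session = session,
                      collapse = collapse)
}

#' Simulate the startle session of one cohort animal and time point
#'
#' @inheritParams true_threshold
#' @param traces Synthesize force traces (`TRUE`) or use the amplitude-level
#'   fast path (`FALSE`); see [simulate_startle_session()].
#' @return A `startle_session` object (deterministic per condition).
#' @export
cohort_startle_session <- function(cohort, animal, session, traces = TRUE) {
  i <- match(animal, cohort$animals$animal)
  if (is.na(i)) stop("unknown animal")
  frac <- cohort_tinnitus_fraction(cohort, cohort$animals$group[i], session)
  truth <- asr_truth(
    baseline_ppi = cohort$ppi[animal, ],
    tinnitus_effect = cohort$config$tinnitus_effect * frac,
    affected_freqs_khz = cohort$animals$affected_freqs_khz[[i]],
    startle_scale = cohort$config$startle_scale,
    startle_sdlog = cohort$config$startle_sdlog,
    artifact_rate = cohort$config$artifact_rate
  )
  simulate_startle_session(truth,
                           n_per_condition = cohort$config$n_per_condition,
                           seed = child_seed(cohort$config$seed, "asr",
                                             animal, session),
                           animal_id = animal, session = session,
                           traces = traces)
}

#' Estimate ABR thresholds across a cohort (trace-level)
#'
#' For every requested animal x session x ear x frequency cell, simulates the
#' full level series of epoch sets, averages them, and runs the automatic
#' threshold rule of [detect_threshold()]. This is the trace-level analysis
#' path; it is compute-heavy (one level series is `n_reps` x 19 epochs).
#'
#' @param cohort A [make_cohort()] result.
#' @param sessions,ears,frequencies_khz,animals Subsets of the cohort grid;
#'   defaults cover the named sessions, the left ear and all configured
#'   frequencies and animals.
#' @param n_reps Repetitions per condition (defaults to the config).
#' @param collapse Use the collapsed epoch-average fast path (default
#'   `TRUE`; exactly equivalent in distribution, see
#'   [simulate_abr_epochs()]).
#' @return Long data frame: `animal`, `group`, `session`, `ear`,
#'   `frequency_khz`, `threshold_db` (NA where detection failed),
#'   `true_threshold_db`.
#' @export
estimate_cohort_thresholds <- function(cohort,
                                       sessions = c("pre_trauma", "post_trauma"),
                                       ears = "left",
                                       frequencies_khz = cohort$config$abr_frequencies_khz,
                                       animals = cohort$animals$animal,
                                       n_reps = cohort$config$n_reps,
                                       collapse = TRUE) {
  grid <- expand.grid(animal = animals, session = sessions, ear = ears,
                      frequency_khz = frequencies_khz,
                      stringsAsFactors = FALSE)
  grid$group <- cohort$animals$group[match(grid$animal, cohort$animals$animal)]
  grid$threshold_db <- NA_real_
  grid$true_threshold_db <- NA_real_
  levels <- cohort$config$levels_db
  for (r in seq_len(nrow(grid))) {
    series <- lapply(levels, function(L) {
      ep <- cohort_abr_epochs(cohort, grid$animal[r], grid$session[r],
                              grid$ear[r], grid$frequency_khz[r], L,
                              n_reps = n_reps, collapse = collapse)
      tr <- average_epochs(ep)
      attr(tr, "onset_sample") <- ep$onset_sample
      attr(tr, "sampling_rate") <- ep$sampling_rate
      tr
    })
    names(series) <- levels
    grid$threshold_db[r] <- detect_threshold(series)
    grid$true_threshold_db[r] <- true_threshold(cohort, grid$animal[r],
                                                grid$ear[r],
                                                grid$frequency_khz[r],
                                                grid$session[r])
  }
  grid[, c("animal", "group", "session", "ear", "frequency_khz",
           "threshold_db", "true_threshold_db")]
}

#' Extract RMS and wave features across a cohort (trace-level)
#'
#' Simulates averaged traces for the requested conditions and levels and
#' computes the response RMS and, at each level, the wave feature set.
#'
#' @inheritParams estimate_cohort_thresholds
#' @param levels_db Stimulus levels to analyze (default 50, 70, 90 dB SPL).
#' @return List of two long data frames: `rms` (`animal`, `group`, `session`,
#'   `ear`, `frequency_khz`, `level_db`, `rms_mv`) and `waves` (adds `wave`,
#'   `latency_ms`, `peak_to_peak_mv`).
#' @export
extract_cohort_features <- function(cohort,
                                    sessions = c("pre_trauma", "post_trauma", "week3"),
                                    ears = "left",
                                    frequencies_khz = cohort$config$abr_frequencies_khz,
                                    animals = cohort$animals$animal,
                                    levels_db = c(50, 70, 90),
                                    n_reps = cohort$config$n_reps,
                                    collapse = TRUE) {
  grid <- expand.grid(animal = animals, session = sessions, ear = ears,
                      frequency_khz = frequencies_khz, level_db = levels_db,
                      stringsAsFactors = FALSE)
  grid$group <- cohort$animals$group[match(grid$animal, cohort$animals$animal)]
  rms <- grid
  rms$rms_mv <- NA_real_
  waves_list <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    ep <- cohort_abr_epochs(cohort, grid$animal[r], grid$session[r],
                            grid$ear[r], grid$frequency_khz[r],
                            grid$level_db[r], n_reps = n_reps,
                            collapse = collapse)
    tr <- average_epochs(ep)
    rms$rms_mv[r] <- compute_rms(tr, ep$onset_sample, ep$sampling_rate)
    wf <- suppressWarnings(detect_waves(tr, ep$onset_sample, ep$sampling_rate,
                                        level_db = grid$level_db[r]))
    wf <- cbind(grid[r, , drop = FALSE], wf, row.names = NULL)
    waves_list[[r]] <- wf
  }
  list(rms = rms[, c("animal", "group", "session", "ear", "frequency_khz",
                     "level_db", "rms_mv")],
       waves = do.call(rbind, waves_list)[, c("animal", "group", "session",
                                              "ear", "frequency_khz",
                                              "level_db", "wave",
                                              "latency_ms", "peak_to_peak_mv")])
}

#' Score tinnitus across a cohort
#'
#' Classifies every animal at the requested post-trauma sessions against its
#' own pre-trauma session with [classify_tinnitus()].
#'
#' @inheritParams estimate_cohort_thresholds
#' @param traces Use trace-level sessions (`TRUE`) or the amplitude-level
#'   fast path.
#' @param alpha Per-frequency significance level (default 0.025).
#' @return Long data frame: `animal`, `group`, `session`, `n_affected`,
#'   `true_tinnitus` (ground-truth percept presence at that session).
#' @export
score_cohort_tinnitus <- function(cohort,
                                  sessions = c("week1", "week2", "week3", "week4"),
                                  animals = cohort$animals$animal,
                                  traces = FALSE, alpha = 0.025) {
  grid <- expand.grid(animal = animals, session = sessions,
                      stringsAsFactors = FALSE)
  grid$group <- cohort$animals$group[match(grid$animal, cohort$animals$animal)]
  grid$n_affected <- NA_integer_
  grid$true_tinnitus <- NA
  pre_cache <- list()
  for (r in seq_len(nrow(grid))) {
    a <- grid$animal[r]
    if (is.null(pre_cache[[a]])) {
      pre_cache[[a]] <- cohort_startle_session(cohort, a, "pre_trauma",
                                               traces = traces)
    }
    post <- cohort_startle_session(cohort, a, grid$session[r], traces = traces)
    ta <- classify_tinnitus(pre_cache[[a]], post, alpha = alpha)
    grid$n_affected[r] <- attr(ta, "n_affected")
    i <- match(a, cohort$animals$animal)
    grid$true_tinnitus[r] <- cohort$animals$tinnitus_positive[i] &&
      cohort_tinnitus_fraction(cohort, grid$group[r], grid$session[r]) > 0
  }
  grid[, c("animal", "group", "session", "n_affected", "true_tinnitus")]
}

#' Fast feature-level threshold table for power studies
#'
#' Emits estimated thresholds for a cohort without synthesizing traces: the
#' session's true threshold plus one-grid-step measurement jitter (the
#' trace-level estimator of [estimate_cohort_thresholds()] recovers true
#' thresholds within one 5 dB step, with a small constant positive offset
#' that cancels in all session/group contrasts). Intended for replicated
#' statistical power and specificity studies where the trace-level path
#' would dominate runtime; the trace-level estimator itself is validated
#' separately.
#'
#' @inheritParams estimate_cohort_thresholds
#' @param seed Seed for the measurement jitter.
#' @return Same shape as [estimate_cohort_thresholds()].
#' @export
simulate_threshold_features <- function(cohort,
                                        sessions = c("pre_trauma", "post_trauma", "week3"),
                                        ears = "left",
                                        frequencies_khz = cohort$config$abr_frequencies_khz,
                                        seed = child_seed(cohort$config$seed, "thrfeat")) {
  grid <- expand.grid(animal = cohort$animals$animal, session = sessions,
                      ear = ears, frequency_khz = frequencies_khz,
                      stringsAsFactors = FALSE)
  grid$group <- cohort$animals$group[match(grid$animal, cohort$animals$animal)]
  grid$true_threshold_db <- mapply(function(a, e, f, s) {
    true_threshold(cohort, a, e, f, s)
  }, grid$animal, grid$ear, grid$frequency_khz, grid$session)
  set.seed(seed)
  jitter <- sample(c(-5, 0, 5), nrow(grid), replace = TRUE,
                   prob = c(0.1, 0.7, 0.2))
  grid$threshold_db <- grid$true_threshold_db + 5 + jitter
  grid[, c("animal", "group", "session", "ear", "frequency_khz",
           "threshold_db", "true_threshold_db")]
}
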