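#' ABR stimulus specification
#'
#' @param kind `"tone"` or `"click"`.
#' @param frequency_khz Tone frequency in kHz on the half-octave 0.5-16 kHz
#'   grid; ignored for clicks.
#' @param level_db Stimulus level in dB SPL on the 0-90 / 5 dB grid.
#' @param duration_ms Stimulus duration (4 ms tone, 0.1 ms click).
#' @param ramp_ms Cosine-squared rise/fall time (1 ms for tones).
#' @return A `stimulus_spec` list.
#' @export
stimulus_spec <- function(kind = c("tone", "click"), frequency_khz = NULL,
                          level_db, duration_ms = NULL, ramp_ms = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(level_db) || length(level_db) != 1 ||
      !(level_db %in% abr_level_grid())) {
    stop("level_db must be a single value on the 0-90 dB SPL grid (5 dB steps)")
  }
  if (kind == "tone") {
    if (is.null(frequency_khz) ||
        !any(abs(frequency_khz - abr_frequency_grid()) < 1e-6)) {
      stop("tone frequency_khz must lie on the 0.5-16 kHz half-octave grid")
    }
    if (is.null(duration_ms)) duration_ms <- 4
    if (is.null(ramp_ms)) ramp_ms <- 1
  } else {
    frequency_khz <- NA_real_
    if (is.null(duration_ms)) duration_ms <- 0.1
    if (is.null(ramp_ms)) ramp_ms <- 0
  }
  structure(list(kind = kind, frequency_khz = frequency_khz,
                 level_db = level_db, duration_ms = duration_ms,
                 ramp_ms = ramp_ms),
            class = "stimulus_spec")
}

#' Ground-truth ABR response model for one ear and frequency
#'
#' Parameterizes the evoked response used by [simulate_abr_epochs()]: a true
#' threshold plus, for each of the four wave complexes (I/II, III, IV, V), an
#' amplitude growth function and a latency function of stimulus level.
#'
#' Amplitude grows logistically with level above threshold and saturates near
#' 90 dB: `a_w(L) = A_w / (1 + exp(-((L - thr) - 15) / 6))` for `L > thr`,
#' zero at and below threshold. Latency decreases linearly with level,
#' `l_w(L) = l70_w + slope * (70 - L)`, clipped below at 0.2 ms after onset.
#' Latencies are strictly increasing with wave index at any level.
#'
#' @param threshold_db True hearing threshold in dB SPL.
#' @param wave_amp_mv Saturating peak-to-peak amplitudes (mV) for waves
#'   I/II, III, IV, V.
#' @param wave_lat70_ms Latencies (ms after onset) of the four waves at
#'   70 dB SPL; must be strictly increasing.
#' @param lat_slope_ms_per_db Latency decrease per dB of level (default
#'   0.012 ms/dB).
#' @param noise_sd_mv Single-epoch noise SD in mV (after band-limiting).
#' @return An `abr_truth` list with `amplitude(level)` and `latency(level)`
#'   accessors.
#' @export
abr_truth <- function(threshold_db,
                      wave_amp_mv = c(0.6, 0.45, 0.9, 0.7),
                      wave_lat70_ms = c(1.6, 2.7, 3.7, 5.2),
                      lat_slope_ms_per_db = 0.012,
                      noise_sd_mv = 0.15) {
  stopifnot(length(wave_amp_mv) == 4, length(wave_lat70_ms) == 4,
            all(diff(wave_lat70_ms) > 0), all(wave_amp_mv >= 0),
            noise_sd_mv >= 0)
  tr <- list(threshold_db = threshold_db,
             wave_amp_mv = wave_amp_mv,
             wave_lat70_ms = wave_lat70_ms,
             lat_slope_ms_per_db = lat_slope_ms_per_db,
             noise_sd_mv = noise_sd_mv)
  tr$amplitude <- function(level_db) {
    x <- level_db - tr$threshold_db
    if (x <= 0) return(rep(0, 4))
    tr$wave_amp_mv / (1 + exp(-(x - 15) / 6))
  }
  tr$latency <- function(level_db) {
    pmax(0.2, tr$wave_lat70_ms + tr$lat_slope_ms_per_db * (70 - level_db))
  }
  class(tr) <- "abr_truth"
  tr
}

#' Wave names of the four ABR wave complexes
#' @return `c("I/II", "III", "IV", "V")`.
#' @export
abr_wave_names <- function() c("I/II", "III", "IV", "V")

# One-cycle sine under a Hann window, sampled at fs for carrier f0, scaled
# and positioned so that the dominant positive peak falls on `peak_index`
# (1-based) and the peak-to-peak amplitude equals `ptp`. Returns a list with
# the sample vector and the index of its first sample.
wave_pulse <- function(fs, f0, peak_index, ptp) {
  n <- max(3L, round(fs / f0))
  k <- seq_len(n)
  shape <- sin(pi * (k - 1) / (n - 1))^2 * sin(2 * pi * (k - 1) / (n - 1))
  shape <- shape * (ptp / (max(shape) - min(shape)))
  list(samples = shape, start = peak_index - (which.max(shape) - 1L))
}

# Variance gain of zero-phase band-pass filtering white noise, cached per
# filter design. Computed from the energy of the filtfilt impulse response.
.nt_cache <- new.env(parent = emptyenv())

abr_bandpass <- function(fs = 10000, band_hz = c(400, 2000), order = 4) {
  key <- paste(fs, band_hz[1], band_hz[2], order, sep = "_")
  if (is.null(.nt_cache[[key]])) {
    bf <- signal::butter(order, band_hz / (fs / 2), type = "pass")
    imp <- c(rep(0, 2048), 1, rep(0, 2048))
    h <- signal::filtfilt(bf, imp)
    .nt_cache[[key]] <- list(filter = bf, sd_gain = sqrt(sum(h^2)))
  }
  .nt_cache[[key]]
}

#' Simulate an ABR epoch set for one stimulus condition
#'
#' Generates `n_reps` single-epoch voltage traces at 10 kHz sampling: a 200 ms
#' pre-stimulus baseline followed by the evoked response, which is the sum
#' over the four wave complexes of a stereotyped pulse (one-cycle 700 Hz sine
#' under a Hann window, inside the 400-2000 Hz recording passband) whose
#' positive peak lies at the wave's true latency and whose peak-to-peak
#' height follows the truth model's amplitude growth function. Independent
#' Gaussian noise, band-limited to emulate the 400-2000 Hz hardware filter,
#' is added per epoch. Below the true threshold there is no evoked component.
#'
#' @param truth An [abr_truth()] model.
#' @param stimulus A [stimulus_spec()]; its level must be on the 5 dB grid.
#' @param n_reps Number of repetitions (>= 1; the acquisition protocol uses
#'   120).
#' @param seed Integer seed; the epoch set is deterministic given it.
#' @param animal_id,ear,session Optional metadata carried on the result.
#' @param collapse If `TRUE`, return the epoch *average* directly as a
#'   single trace instead of materializing `n_reps` epochs. Because epoch
#'   averaging is linear, the average of `n_reps` independent band-limited
#'   noise epochs is exactly one band-limited noise trace with SD
#'   `noise_sd / sqrt(n_reps)`, so this path is distributionally identical
#'   to averaging a materialized set while costing `1/n_reps` the memory and
#'   time; cohort-scale feature extraction uses it.
#' @return An `abr_epochs` object: list with `traces` (`n_reps` x samples
#'   matrix, mV; one row with attribute-recorded `collapsed_reps` when
#'   `collapse = TRUE`), `sampling_rate` (10000), `onset_sample` (1-based
#'   index of the first post-onset sample), `stimulus` and metadata.
#' @export
simulate_abr_epochs <- function(truth, stimulus, n_reps = 120, seed = 1L,
                                animal_id = NA_character_, ear = NA_character_,
                                session = NA_character_, collapse = FALSE) {
  if (!inherits(stimulus, "stimulus_spec")) stop("stimulus must be a stimulus_spec")
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1) stop("n_reps must be >= 1")
  fs <- 10000
  onset_sample <- 2001L           # 200 ms baseline before stimulus onset
  n_post <- 150L                  # 15 ms after onset
  n_samples <- onset_sample - 1L + n_post

  signal_tr <- numeric(n_samples)
  amps <- truth$amplitude(stimulus$level_db)
  lats <- truth$latency(stimulus$level_db)
  for (w in seq_len(4)) {
    if (amps[w] <= 0) next
    peak_idx <- onset_sample + as.integer(round(lats[w] * fs / 1000))
    p <- wave_pulse(fs, 700, peak_idx, amps[w])
    idx <- p$start + seq_along(p$samples) - 1L
    keep <- idx >= 1L & idx <= n_samples
    signal_tr[idx[keep]] <- signal_tr[idx[keep]] + p$samples[keep]
  }

  n_rows <- if (collapse) 1L else n_reps
  sd_row <- if (collapse) truth$noise_sd_mv / sqrt(n_reps) else truth$noise_sd_mv
  traces <- matrix(rep(signal_tr, each = n_rows), nrow = n_rows)
  if (sd_row > 0) {
    bp <- abr_bandpass(fs)
    set.seed(seed)
    white <- rnorm(n_rows * n_samples, sd = sd_row / bp$sd_gain)
    noise <- signal::filtfilt(bp$filter, white)
    traces <- traces + matrix(noise, nrow = n_rows, byrow = TRUE)
  }
  if (collapse) attr(traces, "collapsed_reps") <- n_reps

  structure(list(traces = traces, sampling_rate = fs,
                 onset_sample = onset_sample, stimulus = stimulus,
                 animal_id = animal_id, ear = ear, session = session),
            class = "abr_epochs")
}

#' @export
print.abr_epochs <- function(x, ...) {
  cat(sprintf("<abr_epochs> %d x %d samples @ %d Hz, %s %s dB",
              nrow(x$traces), ncol(x$traces), x$sampling_rate,
              if (x$stimulus$kind == "tone")
                paste0(x$stimulus$frequency_khz, " kHz") else "click",
              x$stimulus$level_db))
  if (!is.na(x$animal_id)) cat(sprintf(" [%s %s %s]", x$animal_id, x$ear, x$session))
  cat("\n")
  invisible(x)
}
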