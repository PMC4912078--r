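#' Validate a startle trial against pre-stimulus movement
#'
#' A trial is invalid when the RMS of its force trace over the 100 ms window
#' before startle onset exceeds `k` times the sensor noise floor (strict
#' inequality: a pre-window exactly at the floor is valid). This is an
#' algorithmic stand-in for by-eye screening of movement artifacts.
#'
#' @param trace Force-sensor trace (numeric vector).
#' @param onset_sample 1-based index of the first post-onset sample.
#' @param sampling_rate Sampling rate in Hz (20000 for startle recordings).
#' @param noise_floor Sensor noise floor (RMS, sensor units).
#' @param k Multiplier on the noise floor (default 3).
#' @return `TRUE` when the trial is valid.
#' @export
validate_trial <- function(trace, onset_sample, sampling_rate = 20000,
                           noise_floor, k = 3) {
  idx <- ms_window_idx(onset_sample, sampling_rate, -100, 0, length(trace))
  sqrt(mean(trace[idx]^2)) <= k * noise_floor
}

#' Peak-to-peak startle amplitude
#'
#' Maximum minus minimum of the force trace over the first 50 ms after
#' startle stimulus onset (half-open window).
#'
#' @inheritParams validate_trial
#' @return Peak-to-peak amplitude in sensor units.
#' @export
startle_amplitude <- function(trace, onset_sample, sampling_rate = 20000) {
  idx <- ms_window_idx(onset_sample, sampling_rate, 0, 50, length(trace))
  max(trace[idx]) - min(trace[idx])
}

#' Robust estimate of a session's sensor noise floor
#'
#' Median across trials of the pre-stimulus-window RMS. Movement artifacts
#' inflate the pre-window RMS of a minority of trials only, so the median
#' tracks the clean-sensor floor.
#'
#' @param session A `startle_session` with traces.
#' @return Noise floor estimate in sensor units.
#' @export
estimate_noise_floor <- function(session) {
  if (is.null(session$traces)) stop("session has no traces")
  idx <- ms_window_idx(session$onset_sample, session$sampling_rate, -100, 0,
                       ncol(session$traces))
  stats::median(apply(session$traces[, idx, drop = FALSE], 1,
                      function(x) sqrt(mean(x^2))))
}

#' Score all trials of a startle session
#'
#' Runs trial validation and peak-to-peak extraction on every trial. For
#' amplitude-level sessions (simulated without traces) the precomputed
#' amplitude and validity are passed through.
#'
#' @param session A `startle_session`.
#' @param k Movement-detection multiplier for [validate_trial()].
#' @param noise_floor Sensor noise floor; estimated from the session via
#'   [estimate_noise_floor()] when `NULL`.
#' @return The trials data frame with `valid` and `amplitude` columns
#'   (`amplitude` is `NA` for invalid trials).
#' @export
score_session <- function(session, k = 3, noise_floor = NULL) {
  trials <- session$trials
  if (is.null(session$traces)) {
    if (is.null(trials$amplitude)) stop("session has neither traces nor amplitudes")
    trials$amplitude[!trials$valid] <- NA_real_
    return(trials)
  }
  if (is.null(noise_floor)) noise_floor <- estimate_noise_floor(session)
  n <- nrow(trials)
  valid <- logical(n)
  amp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    valid[i] <- validate_trial(session$traces[i, ], session$onset_sample,
                               session$sampling_rate, noise_floor, k)
    if (valid[i]) {
      amp[i] <- startle_amplitude(session$traces[i, ], session$onset_sample,
                                  session$sampling_rate)
    }
  }
  trials$valid <- valid
  trials$amplitude <- amp
  trials
}

#' Per-frequency prepulse inhibition of a startle session
#'
#' PPI at each startle frequency from the valid trials:
#' `ppi = (1 - mean(gap amplitudes) / mean(no-gap amplitudes)) * 100`.
#' A frequency with no valid no-gap trial, no valid gap trial, or a
#' non-positive mean no-gap amplitude is flagged missing.
#'
#' @param session A `startle_session`, or a scored trials data frame from
#'   [score_session()].
#' @param ... Passed to [score_session()] when `session` is a session object.
#' @return A `ppi_result` data frame: `frequency_khz`, `ppi`, `n_valid_gap`,
#'   `n_valid_nogap`.
#' @export
session_ppi <- function(session, ...) {
  scored <- if (inherits(session, "startle_session")) {
    score_session(session, ...)
  } else session
  freqs <- sort(unique(scored$frequency_khz))
  out <- data.frame(frequency_khz = freqs, ppi = NA_real_,
                    n_valid_gap = 0L, n_valid_nogap = 0L)
  for (i in seq_along(freqs)) {
    sub <- scored[scored$frequency_khz == freqs[i] & scored$valid, , drop = FALSE]
    g <- sub$amplitude[sub$gap]
    ng <- sub$amplitude[!sub$gap]
    out$n_valid_gap[i] <- length(g)
    out$n_valid_nogap[i] <- length(ng)
    if (length(g) >= 1 && length(ng) >= 1 && mean(ng) > 0) {
      out$ppi[i] <- (1 - mean(g) / mean(ng)) * 100
    }
  }
  class(out) <- c("ppi_result", "data.frame")
  out
}
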