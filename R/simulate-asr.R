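#' Ground-truth startle/PPI model for one animal and session
#'
#' @param baseline_ppi Named numeric vector: baseline gap-PPI in percent per
#'   startle frequency (names = frequency in kHz), each in `[0, 100)`.
#' @param tinnitus_effect Multiplicative PPI reduction applied at affected
#'   frequencies (0 = no percept, 1 = gap inhibition fully abolished).
#' @param affected_freqs_khz Frequencies at which the percept degrades
#'   gap-PPI (subset of [startle_frequencies()]).
#' @param startle_scale Median no-gap startle peak-to-peak amplitude
#'   (force-sensor units).
#' @param startle_sdlog Lognormal log-scale SD of trial amplitudes.
#' @param artifact_rate Probability of pre-stimulus movement per trial.
#' @return An `asr_truth` list with an `effective_ppi(freq)` accessor.
#' @export
asr_truth <- function(baseline_ppi,
                      tinnitus_effect = 0,
                      affected_freqs_khz = numeric(0),
                      startle_scale = 100,
                      startle_sdlog = 0.3,
                      artifact_rate = 0.1) {
  stopifnot(all(baseline_ppi >= 0), all(baseline_ppi < 100),
            artifact_rate >= 0, artifact_rate < 1,
            tinnitus_effect >= 0, tinnitus_effect <= 1)
  tr <- list(baseline_ppi = baseline_ppi,
             tinnitus_effect = tinnitus_effect,
             affected_freqs_khz = affected_freqs_khz,
             startle_scale = startle_scale,
             startle_sdlog = startle_sdlog,
             artifact_rate = artifact_rate)
  tr$effective_ppi <- function(freq_khz) {
    ppi <- tr$baseline_ppi[[as.character(freq_khz)]]
    if (freq_khz %in% tr$affected_freqs_khz) {
      ppi <- ppi * (1 - tr$tinnitus_effect)
    }
    ppi
  }
  class(tr) <- "asr_truth"
  tr
}

# Unit startle response shape at 20 kHz: a damped oscillation beginning
# ~4 ms after stimulus onset (motor latency) and decaying within ~40 ms,
# scaled later so its peak-to-peak equals the drawn trial amplitude.
startle_shape <- function(fs = 20000, n_post = 1200L) {
  t <- (seq_len(n_post) - 1) / fs
  lat <- 0.004
  u <- pmax(0, t - lat)
  s <- exp(-u / 0.008) * sin(2 * pi * 60 * u) * (t >= lat)
  s / (max(s) - min(s))
}

#' Simulate a gap-PPI startle session
#'
#' For each of the five startle frequencies and both gap conditions,
#' generates `n_per_condition` force-sensor traces at 20 kHz: baseline sensor
#' noise, a startle response whose peak-to-peak amplitude is drawn from a
#' lognormal distribution scaled by the truth's `startle_scale`, and -- in
#' gap trials -- attenuated by the factor `1 - effective_ppi / 100`.
#' With probability `artifact_rate` a trial additionally contains a movement
#' burst inside the 100 ms pre-stimulus window (at ten times the sensor noise
#' floor), which trial validation is expected to discard.
#'
#' @param truth An [asr_truth()] model.
#' @param n_per_condition Trials per frequency x gap condition (>= 1).
#' @param seed Integer seed; the session is deterministic given it.
#' @param animal_id,session Optional metadata.
#' @param traces If `FALSE`, skip waveform synthesis and carry the drawn
#'   amplitudes directly (`amplitude` column), with validity equal to the
#'   absence of a movement artifact. This amplitude-level fast path is used
#'   for large calibration studies; its equivalence to trace-level extraction
#'   is established by the test suite.
#' @return A `startle_session` object: `trials` data frame (`frequency_khz`,
#'   `gap`, `trial`), `traces` matrix (one row per trial; `NULL` in fast
#'   mode), `sampling_rate`, `onset_sample`, plus hidden ground truth in
#'   `attr(, "truth_trials")` (never read by analysis code).
#' @export
simulate_startle_session <- function(truth, n_per_condition = 15, seed = 1L,
                                     animal_id = NA_character_,
                                     session = NA_character_,
                                     traces = TRUE) {
  n_per_condition <- as.integer(n_per_condition)
  if (is.na(n_per_condition) || n_per_condition < 1) {
    stop("n_per_condition must be >= 1")
  }
  fs <- 20000
  onset_sample <- 2001L           # 100 ms pre-stimulus window
  n_post <- 1200L                 # 60 ms after onset
  n_samples <- onset_sample - 1L + n_post
  noise_sd <- 1                   # sensor noise floor, force-sensor units

  freqs <- startle_frequencies()
  grid <- expand.grid(trial = seq_len(n_per_condition),
                      gap = c(FALSE, TRUE), frequency_khz = freqs)
  grid <- grid[, c("frequency_khz", "gap", "trial")]
  n_trials <- nrow(grid)

  set.seed(seed)
  amp <- rlnorm(n_trials, meanlog = log(truth$startle_scale),
                sdlog = truth$startle_sdlog)
  eff <- vapply(grid$frequency_khz, truth$effective_ppi, numeric(1))
  amp <- amp * ifelse(grid$gap, 1 - eff / 100, 1)
  artifact <- runif(n_trials) < truth$artifact_rate

  trace_mat <- NULL
  if (traces) {
    shape <- startle_shape(fs, n_post)
    trace_mat <- matrix(rnorm(n_trials * n_samples, sd = noise_sd),
                        nrow = n_trials)
    post_idx <- onset_sample:n_samples
    for (i in seq_len(n_trials)) {
      trace_mat[i, post_idx] <- trace_mat[i, post_idx] + amp[i] * shape
      if (artifact[i]) {
        # 50 ms movement burst centered ~55 ms before stimulus onset
        burst_idx <- (onset_sample - 1600L):(onset_sample - 601L)
        win <- sin(pi * seq_along(burst_idx) / length(burst_idx))^2
        trace_mat[i, burst_idx] <- trace_mat[i, burst_idx] +
          rnorm(length(burst_idx), sd = 10 * noise_sd) * win
      }
    }
  } else {
    grid$amplitude <- amp
    grid$valid <- !artifact
  }

  structure(list(trials = grid, traces = trace_mat, sampling_rate = fs,
                 onset_sample = onset_sample, noise_floor = noise_sd,
                 animal_id = animal_id, session = session),
            class = "startle_session",
            truth_trials = data.frame(amplitude = amp, artifact = artifact))
}

#' @export
print.startle_session <- function(x, ...) {
  cat(sprintf("<startle_session> %d trials (%s)", nrow(x$trials),
              if (is.null(x$traces)) "amplitude-level" else
                sprintf("%d samples @ %d Hz", ncol(x$traces), x$sampling_rate)))
  if (!is.na(x$animal_id)) cat(sprintf(" [%s %s]", x$animal_id, x$session))
  cat("\n")
  invisible(x)
}
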