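#' Session labels of the experimental time course
#'
#' Ordered labels for the measurement sessions: healthy baseline
#' (`pre_trauma`), directly after the noise exposure (`post_trauma`), and the
#' four weekly follow-ups (`week1` .. `week4`). Treatment runs over weeks 1-3;
#' `week4` is the post-treatment follow-up.
#'
#' @return Character vector of the six session labels, in chronological order.
#' @export
time_points <- function() {
  c("pre_trauma", "post_trauma", "week1", "week2", "week3", "week4")
}

#' Startle (tinnitus-test) frequencies in kHz
#' @return Numeric vector `c(1, 2, 4, 8, 16)`.
#' @export
startle_frequencies <- function() c(1, 2, 4, 8, 16)

#' Half-octave ABR stimulus frequency grid in kHz
#' @return Numeric vector from 0.5 to 16 kHz in half-octave steps.
#' @export
abr_frequency_grid <- function() {
  round(0.5 * 2^(seq(0, 5, by = 0.5)), 3)
}

#' ABR stimulus level grid in dB SPL
#' @return `seq(0, 90, by = 5)`.
#' @export
abr_level_grid <- function() seq(0, 90, by = 5)

#' Configuration for a simulated noise-trauma cohort
#'
#' Defines the study design that [make_cohort()] realizes: group sizes, the
#' broadband ("parallel") trauma-induced threshold shift, group-specific
#' recovery during the three treatment weeks, and the tinnitus model (which
#' animals develop a percept, at how many of the five startle frequencies,
#' and how strongly it degrades gap-PPI).
#'
#' The defaults emulate the study design the package targets: 11 treated and
#' 9 vehicle animals, a 14 dB frequency-independent threshold shift, full
#' threshold and tinnitus recovery in the treated group by week 3 (none in
#' the vehicle group), and tinnitus reappearing after treatment ends.
#'
#' @param n_treated,n_vehicle Animals per group (defaults 11 and 9).
#' @param trauma_shift_db Mean broadband threshold shift in dB (default 14).
#' @param trauma_shift_sd_db Between-animal SD of the realized shift
#'   (default 3); each animal's parallel shift is drawn once and rounded to
#'   the 5 dB grid, so true thresholds stay on the audiogram grid.
#' @param recovery_fraction_treated,recovery_fraction_vehicle Fraction of the
#'   shift removed by week 3 in each group, in `[0, 1]`.
#' @param tinnitus_prevalence Probability that an animal develops a tinnitus
#'   percept after the trauma (default 0.75, matching 9/11 and 6/9 positives).
#' @param max_tinnitus_freqs Maximum number of affected startle frequencies
#'   per animal, at most 5 (default 3).
#' @param tinnitus_reappears_week4 Should tinnitus return at week 4 in treated
#'   animals whose percept had resolved (default `TRUE`)?
#' @param abr_frequencies_khz ABR frequencies simulated for the cohort. Must
#'   lie on the half-octave grid [abr_frequency_grid()]. The default octave
#'   subset (0.5-16 kHz) keeps full-cohort simulations tractable.
#' @param levels_db ABR stimulus levels, on the 0-90 dB / 5 dB grid.
#' @param n_reps ABR repetitions per stimulus condition (default 120).
#' @param noise_sd_mv Single-epoch ABR noise SD in mV after band-limiting
#'   (default 0.15; single-epoch SNR near threshold is ~1, so averaging over
#'   repetitions is required, as in real recordings).
#' @param threshold_mean_db,threshold_sd_db Distribution of pre-trauma true
#'   thresholds across animals/ears/frequencies (rounded to the 5 dB grid).
#' @param baseline_ppi_mean,baseline_ppi_sd Distribution of baseline gap-PPI
#'   (percent) across animals and frequencies.
#' @param startle_scale Median no-gap startle peak-to-peak amplitude in
#'   force-sensor units.
#' @param startle_sdlog Log-scale SD of the lognormal trial-to-trial startle
#'   amplitude distribution (default 0.3, i.e. ~30 percent CV).
#' @param tinnitus_effect Multiplicative gap-PPI reduction at affected
#'   frequencies when the percept is fully present (default 0.5).
#' @param artifact_rate Probability that a startle trial contains pre-stimulus
#'   movement (default 0.1).
#' @param n_per_condition Startle trials per frequency x gap condition
#'   (default 15).
#' @param seed Root seed; all per-animal/per-session randomness is derived
#'   deterministically from it.
#' @return A `cohort_config` list, validated.
#' @seealso [make_cohort()]
#' @export
cohort_config <- function(n_treated = 11,
                          n_vehicle = 9,
                          trauma_shift_db = 14,
                          trauma_shift_sd_db = 3,
                          recovery_fraction_treated = 1,
                          recovery_fraction_vehicle = 0,
                          tinnitus_prevalence = 0.75,
                          max_tinnitus_freqs = 3,
                          tinnitus_reappears_week4 = TRUE,
                          abr_frequencies_khz = c(0.5, 1, 2, 4, 8, 16),
                          levels_db = abr_level_grid(),
                          n_reps = 120,
                          noise_sd_mv = 0.15,
                          threshold_mean_db = 45,
                          threshold_sd_db = 7,
                          baseline_ppi_mean = 65,
                          baseline_ppi_sd = 5,
                          startle_scale = 100,
                          startle_sdlog = 0.3,
                          tinnitus_effect = 0.5,
                          artifact_rate = 0.1,
                          n_per_condition = 15,
                          seed = 1L) {
  cfg <- list(
    n_treated = as.integer(n_treated),
    n_vehicle = as.integer(n_vehicle),
    trauma_shift_db = trauma_shift_db,
    trauma_shift_sd_db = trauma_shift_sd_db,
    recovery_fraction_treated = recovery_fraction_treated,
    recovery_fraction_vehicle = recovery_fraction_vehicle,
    tinnitus_prevalence = tinnitus_prevalence,
    max_tinnitus_freqs = as.integer(max_tinnitus_freqs),
    tinnitus_reappears_week4 = isTRUE(tinnitus_reappears_week4),
    abr_frequencies_khz = as.numeric(abr_frequencies_khz),
    levels_db = as.numeric(levels_db),
    n_reps = as.integer(n_reps),
    noise_sd_mv = noise_sd_mv,
    threshold_mean_db = threshold_mean_db,
    threshold_sd_db = threshold_sd_db,
    baseline_ppi_mean = baseline_ppi_mean,
    baseline_ppi_sd = baseline_ppi_sd,
    startle_scale = startle_scale,
    startle_sdlog = startle_sdlog,
    tinnitus_effect = tinnitus_effect,
    artifact_rate = artifact_rate,
    n_per_condition = as.integer(n_per_condition),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_treated >= 0, cfg$n_vehicle >= 0,
    cfg$n_treated + cfg$n_vehicle > 0,
    cfg$recovery_fraction_treated >= 0, cfg$recovery_fraction_treated <= 1,
    cfg$recovery_fraction_vehicle >= 0, cfg$recovery_fraction_vehicle <= 1,
    cfg$tinnitus_prevalence >= 0, cfg$tinnitus_prevalence <= 1,
    cfg$max_tinnitus_freqs >= 1, cfg$max_tinnitus_freqs <= 5,
    cfg$n_reps >= 1, cfg$n_per_condition >= 1,
    cfg$noise_sd_mv >= 0,
    cfg$artifact_rate >= 0, cfg$artifact_rate < 1,
    cfg$tinnitus_effect >= 0, cfg$tinnitus_effect <= 1
  )
  if (!all(cfg$levels_db %in% abr_level_grid())) {
    stop("levels_db must lie on the 0-90 dB SPL grid in 5 dB steps")
  }
  if (!all(sapply(cfg$abr_frequencies_khz, function(f) {
    any(abs(f - abr_frequency_grid()) < 1e-6)
  }))) {
    stop("abr_frequencies_khz must lie on the 0.5-16 kHz half-octave grid")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d treated + %d vehicle animals, trauma shift %g dB\n",
              x$n_treated, x$n_vehicle, x$trauma_shift_db))
  cat(sprintf("  ABR: %d frequencies x %d levels x %d reps, noise %g mV\n",
              length(x$abr_frequencies_khz), length(x$levels_db), x$n_reps,
              x$noise_sd_mv))
  cat(sprintf("  ASR: PPI ~ %g%%, tinnitus effect %g, prevalence %g, seed %d\n",
              x$baseline_ppi_mean, x$tinnitus_effect, x$tinnitus_prevalence,
              x$seed))
  invisible(x)
}

# Fraction of the trauma threshold shift still present at each session.
# Recovery is linear over the treatment weeks: half the recoverable shift is
# gone at week 2, all of it by week 3; it does not rebound afterwards.
shift_profile <- function(recovery_fraction) {
  c(pre_trauma = 0, post_trauma = 1, week1 = 1,
    week2 = 1 - 0.5 * recovery_fraction,
    week3 = 1 - recovery_fraction,
    week4 = 1 - recovery_fraction)
}

# Fraction of the full tinnitus effect present at each session. The percept
# develops during the recovery week (absent in the immediate post-trauma ABR
# session), resolves in step with treatment, and optionally reappears at
# week 4 after treatment ends.
tinnitus_profile <- function(recovery_fraction, reappears_week4) {
  c(pre_trauma = 0, post_trauma = 0, week1 = 1,
    week2 = 1 - 0.5 * recovery_fraction,
    week3 = 1 - recovery_fraction,
    week4 = if (reappears_week4) 1 else 1 - recovery_fraction)
}

# Deterministic child seed from the root seed and a set of labels/indices.
# Keeps values in [1, 2^31 - 2] so they are valid R integer seeds.
child_seed <- function(root, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- as.double(root %% 2147483647L)
  for (p in parts) {
    for (cc in utf8ToInt(p)) {
      h <- (h * 31 + cc) %% 2147483647
    }
  }
  as.integer(h) + 1L
}
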