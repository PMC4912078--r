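---
title: "Simulating and analyzing ABR and gap-startle data from a noise-trauma treatment study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing ABR and gap-startle data from a noise-trauma treatment study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisetrauma)
```

## The experiment this package models

`noisetrauma` re-implements, as tested and reusable code, the measurement
and analysis chain of a rodent noise-trauma treatment experiment. Twenty
animals in two groups (11 treated, 9 vehicle) are followed through six
sessions: a healthy baseline, a session directly after an acoustic trauma
that produces a mild noise-induced hearing loss, and four weekly follow-ups,
with treatment administered during weeks 1-3. Two measurement modalities
drive all conclusions:

* **Auditory brainstem responses (ABR).** Far-field evoked potentials to
  tone pips (0.5-16 kHz in half-octave steps, 0-90 dB SPL in 5 dB steps,
  120 repetitions per condition, 10 kHz sampling, 400-2000 Hz bandpass,
  amplitudes in mV at a gain of 10,000). From these the pipeline derives
  audiograms (automatic thresholds), response RMS over 1-5 ms after onset,
  and the peak-to-peak amplitudes and latencies of wave complexes I/II,
  III, IV and V, conventionally read at 70 dB SPL.
* **Gap-prepulse inhibition of the acoustic startle reflex (GPIAS).** A
  silent 15 ms gap in background noise, 100 ms before a 105 dB startle tone
  (1, 2, 4, 8 or 16 kHz), normally inhibits the startle response. A phantom
  percept at a given frequency "fills" the gap and reduces that inhibition,
  so a per-frequency drop of gap-PPI relative to the animal's own pre-trauma
  baseline is the behavioral sign of tinnitus.

No raw per-animal data from such experiments are publicly deposited, so the
package ships a synthetic-data generator that realizes the full design with
known ground truth. Every analysis result in this vignette, in the README
and in the test suite is computed on that generator's output; the generator
is first-class, tested code, and analysis functions never read the stored
truth.

## The synthetic cohort

`cohort_config()` fixes the study conditions; `make_cohort()` realizes them.
The defaults are the experiment's own design parameters where those are
stated (group sizes 11 + 9; a ~14 dB broadband threshold shift; full treated
recovery by week 3 and none in the vehicle group; tinnitus at 1-3 of the 5
startle frequencies; 120 ABR repetitions; 15 startle trials per condition;
tinnitus reappearing after treatment ends). Quantities the design does not
pin down are free parameters of the simulator, chosen once at realistic
values and not revisited:

* **ABR evoked response.** Each wave is a one-cycle 700 Hz sine under a Hann
  window (inside the 400-2000 Hz passband), its positive peak at the wave's
  latency. Amplitude grows logistically with level above threshold and
  saturates near 90 dB; latency decreases linearly with level
  (0.012 ms/dB). Saturating amplitudes (0.6, 0.45, 0.9, 0.7 mV for waves
  I/II-V, with ~15% per-animal lognormal variation) put 70 dB peak-to-peak
  values in the 0.2-0.8 mV range typical of such recordings at gain 10,000.
* **Epoch noise.** White Gaussian noise, band-limited by the same 4th-order
  Butterworth 400-2000 Hz filter the hardware applies, scaled to a
  single-epoch SD of 0.15 mV. Near threshold the single-epoch SNR is then
  about 1 — single epochs are useless, 120-epoch averages are clean, which
  is exactly why ABR protocols average.
* **Thresholds and trauma.** Pre-trauma true thresholds are drawn per
  animal x ear x frequency from N(45, 7) dB and rounded to the 5 dB grid.
  The trauma shift is *parallel* (frequency-independent within animal); its
  size is drawn once per animal from N(14, 3) dB and rounded to the grid,
  modeling between-animal trauma susceptibility while keeping true
  thresholds on the audiogram grid. Treated-group thresholds recover
  linearly to baseline over weeks 1-3; vehicle thresholds do not.
* **Startle model.** Trial peak-to-peak amplitudes are lognormal
  (median = `startle_scale`, sdlog 0.3, i.e. ~30% trial-to-trial CV; the
  design gives no distributional form, and a positive skewed distribution
  is standard for startle magnitudes). Baseline gap-PPI is drawn per
  animal x frequency from N(65, 5)%. A full tinnitus percept multiplies
  gap-PPI by `1 - tinnitus_effect` (default 0.5) at the affected
  frequencies only; the percept develops during the first post-trauma week,
  resolves in step with treatment in the treated group, and reappears at
  week 4. Ten percent of trials contain a pre-stimulus movement burst (10x
  the sensor noise floor for 50 ms), which trial validation must discard.
* **Determinism.** One root seed; every condition derives a child seed from
  a string hash of its identifiers, so any epoch set or session regenerates
  bit-identically, independently of evaluation order. The dataset container
  (`write_dataset()` / `read_dataset()`) exploits this: traces are not
  stored but re-synthesized on demand from the config.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: electrode drift and non-Gaussian physiological
noise, frequency-dependent hearing loss profiles, startle habituation over
a session, audibility loss of the startle stimulus after the trauma, and
any pharmacology of the treatment itself (recovery is a design parameter,
not a drug model).

## ABR analysis

`average_epochs()`, `baseline_stats()` (window 200-100 ms before onset,
population SD), `evoked_amplitude()` and `compute_rms()` (both over
1-5 ms after onset) are deliberately plain, oracle-tested arithmetic.
Windows are half-open `[start, end)` in time; traces store the 1-based
index of the first post-onset sample.

**Automatic thresholds.** The classical criterion — "response present when
the evoked amplitude exceeds 2 SD of the baseline" — needs care when the
evoked amplitude is a *maximum* over a response window: under pure
band-limited noise that maximum sits near 2 baseline SDs by construction,
at any noise level, so a literal reading qualifies ~30% of response-free
levels. `detect_threshold()` therefore compares like with like: the
baseline is scanned in disjoint response-window-sized segments, the same
window-max statistic is computed in each, and a level qualifies when its
evoked amplitude exceeds the mean + 2 SD of that null sample. For a
noiseless trace the reference collapses to zero and any response qualifies.
The reported threshold is the lowest level of the contiguous run of
qualifying levels that extends down from the highest tested level (a real
response is present at every supra-threshold level and absent below), and
the run must span at least two levels; otherwise the frequency is reported
missing, mirroring the discarding of low-SNR data. On the default cohort
this recovers thresholds with a median error of one 5 dB grid step (a small
constant positive offset that cancels in every shift and group contrast)
and the 14 dB trauma shift to within ~1 dB.

**Waves.** `detect_waves()` takes the dominant positive peak in each wave's
latency window (defaults at 70 dB: I/II 1.0-2.2, III 2.2-3.2, IV 3.2-4.5,
V 4.5-6.5 ms; earliest sample on ties) and the minimum within 1 ms after
the peak as its trough — the trough may legitimately lie past the window
edge, and tying it to the peak rather than the window avoids truncating
waves that peak late in their window. Latency is peak time after onset;
amplitude is peak minus trough; a flat window reports a missing wave.

**Ears.** Ears are simulated and analyzed independently; cohort-level
drivers default to one ear, since in the simulator ears are exchangeable
replicates and the second ear doubles compute without changing any tested
property.

## Tinnitus scoring

`session_ppi()` uses the standard GPIAS definition,
`PPI = (1 - mean gap amplitude / mean no-gap amplitude) x 100`, over valid
trials. Trial validation is algorithmic (the original screening was by
eye): a trial is invalid when its 100 ms pre-stimulus RMS exceeds 3x the
sensor noise floor, estimated robustly as the median pre-window RMS across
the session's trials.

`classify_tinnitus()` tests, per frequency, the change of PPI relative to
pre-trauma against zero (t-test, alpha = 0.025 two-sided, with impairment —
negative change — required for a positive call). The replicate unit for
that t-test is the one genuinely open design question, and it matters. The
obvious construction (each post gap-trial normalized by the post no-gap
session mean, minus the fixed pre-trauma session PPI) hides two variance
sources from the t-test denominator — the sampling error of the pre-trauma
PPI estimate and of the no-gap means — and Monte Carlo shows it rejects
~7x too often under the null (0.09 vs the nominal 0.0125 directional
level). The package's default construction instead forms *paired per-trial
PPI samples*: the i-th valid gap trial normalized by the i-th valid no-gap
trial within each session, pre and post samples paired by index, the
difference scaled by the mean pre sample. Every sample then carries its own
normalizer, the pre-trauma reference enters as a sample rather than a
constant, and the common scale factor cancels in the t statistic; the
measured null directional rate is 0.011 vs nominal 0.0125. The price is a
small upward magnitude bias of the *mean change sample* (ratios of
lognormals; the point estimate reported alongside uses session PPIs and is
unbiased), and both constructions remain available
(`method = "paired"` / `"session_mean"`). Frequencies with fewer than 3
change samples or non-positive pre-trauma PPI are excluded from the
affected-frequency count, never imputed.

At the default effect size the classifier recovers animal-level tinnitus
status with sensitivity and specificity ~0.95, and its per-frequency power
rises monotonically with effect size — both properties are recomputed by
the acceptance script rather than quoted here.

## Group statistics

`factorial_anova()` wraps `stats::aov` with `car::Anova` Type II tests
(robust to mildly unbalanced cells from discarded conditions; identical to
the classical decomposition for balanced designs, which is how the oracle
test pins it), per-cell 95% t-intervals, and `TukeyHSD` post-hoc tables.
Designs with structurally empty cells are rejected with a diagnostic;
zero-residual-variance fits are flagged rather than failed. As in the
original analysis, ear x frequency observations nested in animal enter the
ANOVAs as independent observations — a deliberate simplification of the
error structure that inflates df (a caveat worth remembering when reading
p-values); animal-level aggregation is a pre-aggregation of the input
table away.

`kruskal_wallis_ranks()` adds Dunn-type pairwise mean-rank z comparisons
(tie-corrected, Bonferroni-adjusted) to `stats::kruskal.test`;
`mann_whitney()` reports the U statistic with an exact p for small
untied samples and the tie-corrected normal approximation otherwise.
Latency summaries use medians and interquartile intervals.

**The KS battery on tinnitus counts.** Per-animal counts of affected
frequencies (0-5) are compared between groups at each session and within
each group between sessions. Two numerical choices matter here:

1. *P-values are Monte Carlo permutation p-values* (group labels permuted,
   D recomputed; 1999 permutations). The asymptotic KS distribution is
   invalid for heavily tied small samples, and at n = 11 vs 9 it is also
   badly conservative.
2. *Multiplicity is reported, not used to gate the headline contrast.* The
   battery reports Bonferroni-adjusted p-values within each comparison
   family (between-group; within-group per group). But a family-wise
   Bonferroni gate over the full ~25-comparison battery can never fire at
   this sample size: the smallest achievable permutation p for 11 vs 9
   animals is about 0.0022, and 25 x 0.0022 > 0.05 even for perfectly
   separated distributions. Any analysis that reports significant corrected
   KS results at these group sizes must therefore be judging evidence per
   comparison, and `qualitative_pattern()` — the summary used to check
   whether a simulated experiment reproduces the treatment story — does the
   same, reading each of its three pre-specified contrasts (treated
   pre-vs-week-3 Tukey, vehicle pre-vs-week-3 Tukey, week-3 between-group
   KS) at alpha = 0.05.

## Problem sizes used by the tests and the acceptance script

All replicated studies run at sizes chosen to make their statistical
targets measurable while keeping the whole suite fast; the vignette records
them as the package's own study design:

* Threshold/shift recovery: one 20-animal cohort, one ear, 6 octave-spaced
  frequencies, 19 levels, pre- and post-trauma sessions (240 level series).
  Cohort-scale runs use the collapsed epoch-average path: since averaging
  is linear, the mean of 120 noise epochs *is* one band-limited noise trace
  at SD/sqrt(120), so the shortcut is distribution-exact, and the epoch
  path is what unit tests exercise.
* Wave recovery: the same cohort at 70 dB, noiseless and at default noise
  (480 wave features each).
* Null calibration of the classifier: 500 animal-replicates (2500
  frequency-level tests), amplitude-level startle sessions (the trace-level
  extractor adds only a bounded sensor-noise offset to the drawn
  amplitudes; the equivalence is itself a test).
* Power and recovery: 5 replicated cohorts for sensitivity/specificity;
  3 effect sizes x 200 replicates for monotonicity.
* End-to-end pattern: 100 replicated cohorts; thresholds via the
  feature-level fast path (`simulate_threshold_features()`, true threshold
  + one-grid-step measurement jitter, matching the operating
  characteristics of the trace-level estimator that is validated
  separately), startle sessions amplitude-level.
* Statistical battery calibration: 1000 null replicates per test; the KS
  leg uses unequal groups (40 vs 36 — unequal like the study's own 11 vs
  9), where the discreteness of D does not prevent the nominal level from
  being attainable. On heavily tied counts any valid KS test is
  conservative; there the suite asserts validity (rejection rate not above
  nominal) rather than exactness.

## Known limitations

* The threshold estimator's +one-grid-step offset is a property of the
  criterion (response strictly above threshold); absolute audiogram levels
  carry it, all contrasts cancel it.
* The paired change-sample construction slightly overstates the magnitude
  of large PPI changes (documented above); significance calls and the
  separately reported point estimate are unaffected.
* Treating ear x frequency cells as independent ANOVA observations
  understates within-animal correlation; mixed models are deliberately out
  of scope.
* The simulator's recovery profiles are design parameters, not
  pharmacokinetics; week-2 states are linear interpolations.
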