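# noisetrauma

Simulation and analysis of auditory brainstem responses (ABR) and
gap-startle behavior from rodent noise-trauma treatment experiments.

## The problem

After an acoustic trauma, rodents develop a mild noise-induced hearing loss
and, in many animals, behavioral signs of tinnitus. A treatment study
follows two groups (treated and vehicle) across weekly sessions and asks
three questions: do hearing thresholds recover under treatment, does the
tinnitus percept resolve, and what happens to brainstem processing along
the way? Answering them requires a chain of signal-processing and
statistical steps that are usually buried in lab-internal scripts:

* **ABR audiometry** — average 120 evoked-potential epochs per condition
  (tone pips 0.5-16 kHz, 0-90 dB SPL in 5 dB steps, 10 kHz sampling,
  400-2000 Hz bandpass); detect the hearing threshold automatically as the
  lowest level whose evoked amplitude (max |deviation| from the baseline
  mean over 1-5 ms post-onset) rises above what baseline fluctuations alone
  produce, with a contiguity rule against noise flukes; assemble audiograms
  and threshold shifts; extract response RMS and the peak-to-peak
  amplitudes/latencies of wave complexes I/II, III, IV, V at 70 dB SPL.
* **GPIAS tinnitus scoring** — validate startle trials against pre-stimulus
  movement, extract 50 ms peak-to-peak startle amplitudes, compute
  per-frequency prepulse inhibition `PPI = (1 - gap/no-gap) x 100`, test
  each frequency's PPI change relative to pre-trauma against 0 (t-test,
  alpha = 0.025, impairment direction), and count affected frequencies per
  animal (tinnitus = at least one).
* **Group statistics** — 2- and 3-factorial ANOVAs with Tukey post-hoc
  comparisons, Kruskal-Wallis with pairwise mean-rank tests, Mann-Whitney
  U, and permutation Kolmogorov-Smirnov comparisons of the per-animal
  tinnitus-frequency count distributions.

Raw data from such experiments are typically unpublished, so the package
also contains a first-class synthetic cohort generator with known ground
truth (thresholds, wave parameters, tinnitus status per frequency, effect
sizes) that realizes the full design — 11 treated + 9 vehicle animals, a
~14 dB parallel trauma shift, treated-group recovery over three treatment
weeks, tinnitus reappearing after treatment ends — deterministically from
one seed. Every analysis function is validated by parameter recovery
against that ground truth; the generator's truth record is never read by
analysis code.

## Worked example

The four numbered scripts under `analysis/` run the whole study; each is a
thin driver over package functions and writes its tables under `results/`.

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + dataset container
Rscript analysis/02_abr_features.R      # thresholds, RMS, waves
Rscript analysis/03_tinnitus_scoring.R  # PPI + tinnitus classification
Rscript analysis/04_group_stats.R       # ANOVA/KW/MWU/KS battery
```

Stage 2 prints (default cohort, seed fixed in the script):

```
Mean estimated thresholds (dB SPL):
  group     session threshold_db
1     G post_trauma     64.84848
2     V post_trauma     63.79630
3     G  pre_trauma     49.92424
4     V  pre_trauma     49.25926
5     G       week3     50.30303
6     V       week3     63.33333
Recovered mean trauma shift: 14.75 dB (simulated: 14.50 dB)
```

Both groups lose ~14 dB of sensitivity after the trauma; by week 3 the
treated group (G) is back at its pre-trauma thresholds while the vehicle
group (V) is not. Stage 3 prints the tinnitus counts that drive the KS
battery:

```
Animals with behavioral tinnitus (n_affected >= 1) per group and week:
  group session n_affected
1     G   week1         10
2     V   week1          4
3     G   week2          7
4     V   week2          3
5     G   week3          1
6     V   week3          5
7     G   week4          9
8     V   week4          4
```

Treated animals lose the percept during treatment (10 → 7 → 1) and it
reappears once treatment stops (9 at week 4); vehicle animals are stable.
Stage 4 runs the statistical battery and summarizes the pre-specified
treatment contrasts:

```
Qualitative pattern:
  treated pre vs week3 thresholds recovered (Tukey ns): TRUE
  vehicle pre vs week3 threshold deficit (Tukey sig):  TRUE
  week3 tinnitus counts differ between groups (KS):    TRUE
```

The same machinery is available directly, e.g.:

```r
library(noisetrauma)
coh <- make_cohort(cohort_config(seed = 1))
ep  <- cohort_abr_epochs(coh, "A01", "pre_trauma", "left",
                         frequency_khz = 2, level_db = 70)
tr  <- average_epochs(ep)
detect_waves(tr, ep$onset_sample)      # wave I/II-V latencies + amplitudes
```

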