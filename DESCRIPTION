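Package: noisetrauma
Title: Simulation and Analysis of ABR and Gap-Startle Data from Noise-Trauma
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditory electrophysiology and behavioral tinnitus
    assessment in rodent noise-trauma experiments. Simulates a two-group
    treatment cohort with known ground truth: auditory brainstem response
    (ABR) epoch sets over a frequency-by-level stimulus grid and acoustic
    startle reflex (ASR) sessions under the gap-prepulse-inhibition (GPIAS)
    paradigm. Extracts ABR features (epoch averages, baseline statistics,
    automatic thresholds and audiograms, response RMS, wave I/II-V peak
    amplitudes and latencies), scores startle sessions (trial validation,
    peak-to-peak amplitudes, per-frequency prepulse inhibition), classifies
    behavioral tinnitus from PPI change relative to pre-trauma, and runs the
    group-level statistical battery: factorial ANOVA with Tukey post-hoc
    comparisons, Kruskal-Wallis with pairwise mean-rank tests, Mann-Whitney
    U, and permutation Kolmogorov-Smirnov comparisons of tinnitus-frequency
    count distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
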