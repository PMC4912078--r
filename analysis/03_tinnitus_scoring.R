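#!/usr/bin/env Rscript
# Stage 3: gap-PPI tinnitus scoring. For every animal and post-trauma
# session, scores the startle session (trial validation, peak-to-peak
# amplitudes, per-frequency PPI) and classifies behavioral tinnitus against
# the animal's own pre-trauma session (per-frequency t-tests at alpha =
# 0.025, impairment direction). Writes results/ppi.csv and
# results/tinnitus.csv.

suppressPackageStartupMessages(library(noisetrauma))

coh <- read_dataset("results/dataset")
sessions <- c("week1", "week2", "week3", "week4")

ppi_rows <- list()
tin_rows <- list()
for (a in coh$animals$animal) {
  pre <- cohort_startle_session(coh, a, "pre_trauma")
  ppi_pre <- session_ppi(pre)
  ppi_rows[[length(ppi_rows) + 1]] <-
    cbind(animal = a, session = "pre_trauma", ppi_pre)
  for (s in sessions) {
    post <- cohort_startle_session(coh, a, s)
    ppi_rows[[length(ppi_rows) + 1]] <-
      cbind(animal = a, session = s, session_ppi(post))
    ta <- classify_tinnitus(pre, post)
    tin_rows[[length(tin_rows) + 1]] <-
      data.frame(animal = a, session = s, frequency_khz = ta$frequency_khz,
                 change_pct = ta$change_pct, p_value = ta$p_value,
                 significant = ta$significant,
                 n_affected = attr(ta, "n_affected"))
  }
}
ppi_tab <- do.call(rbind, ppi_rows)
tin_tab <- do.call(rbind, tin_rows)

counts <- unique(tin_tab[, c("animal", "session", "n_affected")])
counts$group <- coh$animals$group[match(counts$animal, coh$animals$animal)]
cat("Animals with behavioral tinnitus (n_affected >= 1) per group and week:\n")
print(stats::aggregate(n_affected ~ group + session, counts,
                       function(x) sum(x >= 1)))

utils::write.csv(ppi_tab, "results/ppi.csv", row.names = FALSE)
utils::write.csv(tin_tab, "results/tinnitus.csv", row.names = FALSE)
cat("wrote results/ppi.csv, results/tinnitus.csv\n")
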