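# Independent brute-force oracles. These deliberately use naive loops and
# first-principles formulas, not the package's code paths.

oracle_col_means <- function(m) {
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    s <- 0
    for (i in seq_len(nrow(m))) s <- s + m[i, j]
    out[j] <- s / nrow(m)
  }
  out
}

oracle_mean_sd_pop <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- 0
  for (xi in x) v <- v + (xi - m)^2
  list(mean = m, sd = sqrt(v / n))
}

oracle_window_max_abs_dev <- function(x, center) {
  best <- -Inf
  for (xi in x) best <- max(best, abs(xi - center))
  best
}

oracle_rms <- function(x) {
  s <- 0
  for (xi in x) s <- s + xi^2
  sqrt(s / length(x))
}

oracle_ptp <- function(x) {
  mx <- -Inf; mn <- Inf
  for (xi in x) { mx <- max(mx, xi); mn <- min(mn, xi) }
  mx - mn
}

# Mann-Whitney U by exhaustive pair counting (ties count 1/2)
oracle_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) {
    u <- u + (x > y) + 0.5 * (x == y)
  }
  u
}

# Two-sample KS D by scanning the pooled support
oracle_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- 0
  for (t in pts) {
    d <- max(d, abs(mean(x <= t) - mean(y <= t)))
  }
  d
}

# Balanced two-way fixed-effects ANOVA from explicit sums of squares
oracle_two_way_anova <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  gm <- mean(y)
  na <- nlevels(a); nb <- nlevels(b)
  n_cell <- length(y) / (na * nb)
  ss_a <- 0
  for (ai in levels(a)) ss_a <- ss_a + sum(a == ai) * (mean(y[a == ai]) - gm)^2
  ss_b <- 0
  for (bi in levels(b)) ss_b <- ss_b + sum(b == bi) * (mean(y[b == bi]) - gm)^2
  ss_cells <- 0; ss_e <- 0
  for (ai in levels(a)) for (bi in levels(b)) {
    cell <- y[a == ai & b == bi]
    ss_cells <- ss_cells + length(cell) * (mean(cell) - gm)^2
    ss_e <- ss_e + sum((cell - mean(cell))^2)
  }
  ss_ab <- ss_cells - ss_a - ss_b
  df_a <- na - 1; df_b <- nb - 1; df_ab <- df_a * df_b
  df_e <- length(y) - na * nb
  ms_e <- ss_e / df_e
  list(F_a = (ss_a / df_a) / ms_e,
       F_b = (ss_b / df_b) / ms_e,
       F_ab = (ss_ab / df_ab) / ms_e,
       df = c(df_a, df_b, df_ab, df_e))
}

# Small fixture helpers -------------------------------------------------

# A trace of given length with known onset, zero everywhere except as set
flat_trace <- function(n = 2150, value = 0) rep(value, n)

# Minimal scored-trials data frame for PPI arithmetic tests
scored_trials <- function(freqs, gap_amps, nogap_amps) {
  do.call(rbind, lapply(seq_along(freqs), function(i) {
    data.frame(
      frequency_khz = freqs[i],
      gap = rep(c(TRUE, FALSE), c(length(gap_amps[[i]]), length(nogap_amps[[i]]))),
      trial = seq_len(length(gap_amps[[i]]) + length(nogap_amps[[i]])),
      valid = TRUE,
      amplitude = c(gap_amps[[i]], nogap_amps[[i]])
    )
  }))
}
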