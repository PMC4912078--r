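# Per-trial PPI samples for one frequency of a scored session: the i-th
# valid gap trial is normalized by the i-th valid no-gap trial, giving
# independent per-trial PPI estimates whose sampling variability is fully
# visible to a t-test (no shared session-mean denominator).
per_trial_ppi <- function(scored, freq_khz) {
  sub <- scored[scored$frequency_khz == freq_khz & scored$valid, , drop = FALSE]
  g <- sub$amplitude[sub$gap]
  ng <- sub$amplitude[!sub$gap]
  m <- min(length(g), length(ng))
  if (m == 0) return(numeric(0))
  g <- g[seq_len(m)]
  ng <- ng[seq_len(m)]
  keep <- ng > 0
  (1 - g[keep] / ng[keep]) * 100
}

#' PPI change relative to pre-trauma
#'
#' For each startle frequency, computes the point estimate
#' `100 * (ppi_post - ppi_pre) / ppi_pre` from the session PPIs and a set of
#' per-trial change samples for the per-frequency t-test.
#'
#' Two change-sample constructions are available. The default (`"paired"`)
#' forms per-trial PPI samples in each session by normalizing the i-th valid
#' gap trial by the i-th valid no-gap trial, pairs pre and post samples by
#' index, and scales the differences by the mean pre sample:
#' `c_i = 100 * (p_post_i - p_pre_i) / mean(p_pre)`. Because each sample
#' carries its own no-gap normalizer and the pre-trauma reference enters as a
#' paired sample rather than a fixed constant, the sample variance of the
#' `c_i` reflects the full sampling variability of the change, and the
#' common scale factor cancels in the t statistic, so the resulting t-test
#' is calibrated. The `"session_mean"` construction (each post gap-trial
#' amplitude normalized by the post no-gap session mean, minus the fixed
#' pre-trauma session PPI) is retained for comparison but anti-conservative:
#' the noise in the pre-trauma PPI estimate and the no-gap means is invisible
#' to the t-test denominator.
#'
#' A frequency whose pre-trauma PPI is not positive, or missing at either
#' time point, is flagged unassessable (no samples, `NA` point estimate).
#'
#' @param pre_session,post_session `startle_session` objects (or scored
#'   trials data frames) for the pre-trauma reference and the session under
#'   test, covering the same frequencies.
#' @param method Change-sample construction, `"paired"` (default) or
#'   `"session_mean"`.
#' @param ... Passed to [score_session()].
#' @return A list with one element per frequency: `samples` (per-trial
#'   normalized change samples, percent), `point_estimate` (percent), and
#'   the session PPIs.
#' @export
ppi_change <- function(pre_session, post_session,
                       method = c("paired", "session_mean"), ...) {
  method <- match.arg(method)
  score <- function(s) {
    if (inherits(s, "startle_session")) score_session(s, ...) else s
  }
  pre <- score(pre_session)
  post <- score(post_session)
  ppi_pre <- session_ppi(pre)
  ppi_post <- session_ppi(post)
  freqs <- intersect(ppi_pre$frequency_khz, ppi_post$frequency_khz)
  out <- lapply(freqs, function(f) {
    p0 <- ppi_pre$ppi[ppi_pre$frequency_khz == f]
    p1 <- ppi_post$ppi[ppi_post$frequency_khz == f]
    res <- list(frequency_khz = f, ppi_pre = p0, ppi_post = p1,
                point_estimate = NA_real_, samples = numeric(0))
    if (is.na(p0) || is.na(p1) || p0 <= 0) return(res)
    res$point_estimate <- 100 * (p1 - p0) / p0
    if (method == "paired") {
      s_pre <- per_trial_ppi(pre, f)
      s_post <- per_trial_ppi(post, f)
      m <- min(length(s_pre), length(s_post))
      if (m >= 1 && mean(s_pre) > 0) {
        res$samples <- 100 * (s_post[seq_len(m)] - s_pre[seq_len(m)]) /
          mean(s_pre)
      }
    } else {
      sub <- post[post$frequency_khz == f & post$valid, , drop = FALSE]
      g <- sub$amplitude[sub$gap]
      ng_mean <- mean(sub$amplitude[!sub$gap])
      p_i <- (1 - g / ng_mean) * 100
      res$samples <- 100 * (p_i - p0) / p0
    }
    res
  })
  names(out) <- as.character(freqs)
  out
}

#' Classify behavioral tinnitus from a gap-PPI session pair
#'
#' Tests, for each startle frequency separately, the per-trial PPI change
#' samples of [ppi_change()] against 0 with a one-sample t-test at
#' `alpha = 0.025` (two-sided). A frequency is significant -- counted as
#' tinnitus-affected -- when `p < alpha` *and* the mean change is negative,
#' i.e. gap-PPI is impaired. Frequencies with fewer than `min_samples`
#' change samples, or unassessable PPI, are excluded from the count (never
#' imputed).
#'
#' @inheritParams ppi_change
#' @param alpha Per-frequency significance level in (0, 1), default 0.025.
#' @param min_samples Minimum change samples per frequency (default 3).
#' @return A `tinnitus_assessment` data frame: `frequency_khz`,
#'   `change_pct` (point estimate), `p_value`, `significant` (logical, `NA`
#'   when unassessable), with attribute `n_affected`.
#' @export
classify_tinnitus <- function(pre_session, post_session, alpha = 0.025,
                              min_samples = 3,
                              method = c("paired", "session_mean"), ...) {
  stopifnot(alpha > 0, alpha < 1)
  ch <- ppi_change(pre_session, post_session, method = method, ...)
  out <- data.frame(frequency_khz = as.numeric(names(ch)),
                    change_pct = NA_real_, p_value = NA_real_,
                    significant = NA)
  for (i in seq_along(ch)) {
    x <- ch[[i]]
    out$change_pct[i] <- x$point_estimate
    if (length(x$samples) < min_samples || is.na(x$point_estimate) ||
        stats::sd(x$samples) == 0) {
      next
    }
    tt <- stats::t.test(x$samples, mu = 0)
    out$p_value[i] <- tt$p.value
    out$significant[i] <- tt$p.value < alpha && mean(x$samples) < 0
  }
  attr(out, "n_affected") <- sum(out$significant, na.rm = TRUE)
  class(out) <- c("tinnitus_assessment", "data.frame")
  out
}

#' @export
print.tinnitus_assessment <- function(x, ...) {
  cat(sprintf("<tinnitus_assessment> %d affected of %d assessable frequencies\n",
              attr(x, "n_affected"), sum(!is.na(x$significant))))
  print.data.frame(x)
  invisible(x)
}
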