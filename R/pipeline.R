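#' Run the full group-level statistical battery
#'
#' Executes, in order, the analyses that summarize a (real or simulated)
#' noise-trauma experiment from its long-format feature tables:
#'
#' 1. Per group: 2-factorial ANOVA of hearing thresholds on
#'    `session x frequency`, with Tukey comparisons of the session means.
#' 2. 3-factorial ANOVA of the response RMS on
#'    `group x session x intensity band` (bands: up to 50 dB SPL vs above).
#' 3. Per ABR wave: 3-factorial ANOVA of peak-to-peak amplitude on
#'    `group x session x level`.
#' 4. Wave latencies: per group, wave and level, Kruskal-Wallis over
#'    sessions with pairwise mean-rank comparisons; between-group
#'    Mann-Whitney U per session, wave and level. Latency summaries use
#'    medians and interquartile intervals.
#' 5. Kolmogorov-Smirnov battery on tinnitus-frequency counts via
#'    [compare_tinnitus_distributions()].
#'
#' Feature-table observations are ear x frequency cells nested in animal,
#' treated as independent observations (a deliberate simplification of the
#' error structure -- see the package vignette; switch to animal-level
#' aggregation by pre-aggregating the input tables). Stages whose inputs are
#' degenerate (e.g. a single animal) are skipped with a note rather than
#' failing the run, so descriptive tables are still produced.
#'
#' @param thresholds Threshold table (`animal`, `group`, `session`, `ear`,
#'   `frequency_khz`, `threshold_db`) or `NULL` to skip stage 1.
#' @param rms RMS table (`..., level_db, rms_mv`) or `NULL`.
#' @param waves Wave feature table (`..., level_db, wave, latency_ms,
#'   peak_to_peak_mv`) or `NULL`.
#' @param tinnitus Tinnitus count table (`animal`, `group`, `session`,
#'   `n_affected`) or `NULL`.
#' @param alpha Significance level for summary flags (default 0.05).
#' @param ks_sessions Sessions entering the KS battery (default: all in the
#'   tinnitus table).
#' @return A `study_report` list with one element per stage plus `notes`.
#' @export
run_study_pipeline <- function(thresholds = NULL, rms = NULL, waves = NULL,
                               tinnitus = NULL, alpha = 0.05,
                               ks_sessions = NULL) {
  if (is.null(thresholds) && is.null(rms) && is.null(waves) &&
      is.null(tinnitus)) {
    stop("no feature tables supplied; need at least one of ",
         "thresholds/rms/waves/tinnitus")
  }
  report <- list(notes = character(0))
  note <- function(stage, e) {
    report$notes <<- c(report$notes, sprintf("%s: %s", stage, conditionMessage(e)))
  }

  if (!is.null(thresholds)) {
    report$threshold_anova <- list()
    for (g in intersect(c("G", "V"), unique(thresholds$group))) {
      sub <- thresholds[thresholds$group == g & !is.na(thresholds$threshold_db), ]
      report$threshold_anova[[g]] <- tryCatch(
        factorial_anova(sub, "threshold_db", c("session", "frequency_khz"),
                        tukey = "session"),
        error = function(e) { note(paste0("threshold_anova_", g), e); NULL })
    }
    report$threshold_means <- stats::aggregate(
      threshold_db ~ group + session, thresholds, mean, na.action = stats::na.omit)
  }

  if (!is.null(rms)) {
    rms$intensity_band <- ifelse(rms$level_db <= 50, "low", "high")
    report$rms_anova <- tryCatch(
      factorial_anova(rms[!is.na(rms$rms_mv), ], "rms_mv",
                      c("group", "session", "intensity_band")),
      error = function(e) { note("rms_anova", e); NULL })
  }

  if (!is.null(waves)) {
    report$wave_amplitude_anova <- list()
    for (w in unique(waves$wave)) {
      sub <- waves[waves$wave == w & !is.na(waves$peak_to_peak_mv), ]
      report$wave_amplitude_anova[[w]] <- tryCatch(
        factorial_anova(sub, "peak_to_peak_mv",
                        c("group", "session", "level_db")),
        error = function(e) { note(paste0("wave_amplitude_anova_", w), e); NULL })
    }
    lat <- waves[!is.na(waves$latency_ms), ]
    report$latency_kw <- list()
    report$latency_mwu <- list()
    if (nrow(lat) > 0) {
      for (g in unique(lat$group)) for (w in unique(lat$wave)) {
        for (L in unique(lat$level_db)) {
          sub <- lat[lat$group == g & lat$wave == w & lat$level_db == L, ]
          if (length(unique(sub$session)) < 2) next
          key <- sprintf("%s wave %s %g dB", g, w, L)
          report$latency_kw[[key]] <- tryCatch(
            kruskal_wallis_ranks(sub$latency_ms, sub$session),
            error = function(e) { note(paste0("latency_kw ", key), e); NULL })
        }
      }
      if (all(c("G", "V") %in% lat$group)) {
        for (s in unique(lat$session)) for (w in unique(lat$wave)) {
          for (L in unique(lat$level_db)) {
            sub <- lat[lat$session == s & lat$wave == w & lat$level_db == L, ]
            a <- sub$latency_ms[sub$group == "G"]
            b <- sub$latency_ms[sub$group == "V"]
            if (length(a) < 1 || length(b) < 1) next
            key <- sprintf("%s wave %s %g dB", s, w, L)
            report$latency_mwu[[key]] <- mann_whitney(a, b)
          }
        }
      }
      report$latency_summary <- stats::aggregate(
        latency_ms ~ group + session + wave + level_db, lat,
        function(x) c(median = stats::median(x),
                      q1 = unname(stats::quantile(x, 0.25)),
                      q3 = unname(stats::quantile(x, 0.75))))
    }
  }

  if (!is.null(tinnitus)) {
    report$tinnitus_ks <- tryCatch(
      compare_tinnitus_distributions(tinnitus, sessions = ks_sessions,
                                     alpha = alpha),
      error = function(e) { note("tinnitus_ks", e); NULL })
    report$tinnitus_counts <- as.data.frame(
      table(group = tinnitus$group, session = tinnitus$session,
            n_affected = tinnitus$n_affected))
  }

  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> stages:",
      paste(setdiff(names(x), "notes"), collapse = ", "), "\n")
  if (length(x$notes)) cat("notes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

# Tukey p-value for one session pair from a threshold ANOVA stage.
tukey_session_p <- function(anova_result, session_a, session_b) {
  if (is.null(anova_result) || is.null(anova_result$tukey)) return(NA_real_)
  tab <- anova_result$tukey[["session"]]
  if (is.null(tab)) return(NA_real_)
  hit <- rownames(tab) %in% c(paste(session_a, session_b, sep = "-"),
                              paste(session_b, session_a, sep = "-"))
  if (!any(hit)) return(NA_real_)
  unname(tab[hit, "p adj"][1])
}

#' Qualitative treatment pattern of a study report
#'
#' Extracts the three headline contrasts that summarize a successful
#' treatment experiment: (1) the treated group's pre-trauma vs post-treatment
#' (week 3) Tukey threshold comparison, expected non-significant after full
#' recovery; (2) the vehicle group's, expected significant; (3) the
#' between-group KS comparison of tinnitus-frequency counts at week 3,
#' expected significant. KS evidence is judged per comparison (raw
#' permutation p): at a 20-animal cohort a family-wise-corrected battery has
#' essentially no power (see vignette).
#'
#' @param report A [run_study_pipeline()] result.
#' @param alpha Significance level (default 0.05).
#' @param post_session Session label of the post-treatment time point
#'   (default `"week3"`).
#' @return List of logicals `treated_recovered`, `vehicle_impaired`,
#'   `tinnitus_differs`, and `pattern` (all three).
#' @export
qualitative_pattern <- function(report, alpha = 0.05, post_session = "week3") {
  pG <- tukey_session_p(report$threshold_anova$G, "pre_trauma", post_session)
  pV <- tukey_session_p(report$threshold_anova$V, "pre_trauma", post_session)
  ks <- report$tinnitus_ks
  pK <- NA_real_
  if (!is.null(ks)) {
    hit <- ks$family == "between_group" & grepl(post_session, ks$comparison)
    if (any(hit)) pK <- ks$p[hit][1]
  }
  out <- list(treated_recovered = !is.na(pG) && pG >= alpha,
              vehicle_impaired = !is.na(pV) && pV < alpha,
              tinnitus_differs = !is.na(pK) && pK < alpha)
  out$pattern <- out$treated_recovered && out$vehicle_impaired &&
    out$tinnitus_differs
  out
}

#' Write a study report to a directory of CSV tables
#'
#' One CSV per analysis stage plus a machine-readable JSON summary of the
#' test statistics.
#'
#' @param report A [run_study_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  anova_rows <- function(lst, stage) {
    do.call(rbind, lapply(names(lst), function(k) {
      if (is.null(lst[[k]])) return(NULL)
      cbind(stage = stage, unit = k, lst[[k]]$table)
    }))
  }
  summ <- list()
  if (!is.null(report$threshold_anova)) {
    tab <- anova_rows(report$threshold_anova, "threshold_anova")
    if (!is.null(tab)) { wr(tab, "threshold_anova"); summ$threshold_anova <- tab }
    wr(report$threshold_means, "threshold_means")
  }
  if (!is.null(report$rms_anova)) {
    wr(cbind(stage = "rms_anova", report$rms_anova$table), "rms_anova")
    summ$rms_anova <- report$rms_anova$table
  }
  if (!is.null(report$wave_amplitude_anova)) {
    tab <- anova_rows(report$wave_amplitude_anova, "wave_amplitude_anova")
    if (!is.null(tab)) { wr(tab, "wave_amplitude_anova"); summ$wave_amplitude_anova <- tab }
  }
  if (!is.null(report$latency_kw) && length(report$latency_kw)) {
    tab <- do.call(rbind, lapply(names(report$latency_kw), function(k) {
      x <- report$latency_kw[[k]]
      if (is.null(x)) return(NULL)
      data.frame(unit = k, H = x$H, df = x$df, p = x$p)
    }))
    if (!is.null(tab)) { wr(tab, "latency_kruskal_wallis"); summ$latency_kw <- tab }
  }
  if (!is.null(report$latency_mwu) && length(report$latency_mwu)) {
    tab <- do.call(rbind, lapply(names(report$latency_mwu), function(k) {
      x <- report$latency_mwu[[k]]
      data.frame(unit = k, U = x$U, p = x$p)
    }))
    wr(tab, "latency_mann_whitney")
    summ$latency_mwu <- tab
  }
  if (!is.null(report$tinnitus_ks)) {
    wr(as.data.frame(report$tinnitus_ks), "tinnitus_ks")
    summ$tinnitus_ks <- as.data.frame(report$tinnitus_ks)
  }
  if (!is.null(report$tinnitus_counts)) wr(report$tinnitus_counts, "tinnitus_counts")
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, "summary.json")))
}
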