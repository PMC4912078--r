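DATASET_SCHEMA_VERSION <- "1.0"

#' Write a cohort dataset to a plain-text directory container
#'
#' Serializes a simulated cohort as an inspectable directory: `meta.json`
#' (schema version), `config.json`, `design.csv` (long-format animal
#' metadata), `truth.json` (ground truth: thresholds, wave parameters,
#' baseline PPI, tinnitus status), and optionally per-condition trace CSVs
#' under `traces/` for a requested subset of conditions (traces are
#' synthesized on demand otherwise; a full cohort's epoch matrices are too
#' large to keep on disk as text).
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param trace_conditions Optional data frame with columns `animal`,
#'   `session`, `ear`, `frequency_khz`, `level_db`: ABR conditions whose
#'   epoch matrices are materialized as CSV.
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(cohort, dir, trace_conditions = NULL) {
  stopifnot(inherits(cohort, "noise_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(schema_version = DATASET_SCHEMA_VERSION,
                            class = "noise_cohort"),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  jsonlite::write_json(unclass(cohort$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  design <- cohort$animals
  design$affected_freqs_khz <- vapply(design$affected_freqs_khz,
                                      paste, character(1), collapse = ";")
  utils::write.csv(design, file.path(dir, "design.csv"), row.names = FALSE)
  truth <- list(abr = cohort$abr,
                wave_params = cohort$wave_params,
                ppi = as.data.frame(cohort$ppi))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  if (!is.null(trace_conditions)) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (r in seq_len(nrow(trace_conditions))) {
      tc <- trace_conditions[r, ]
      ep <- cohort_abr_epochs(cohort, tc$animal, tc$session, tc$ear,
                              tc$frequency_khz, tc$level_db)
      fn <- sprintf("abr_%s_%s_%s_%gkHz_%gdB.csv", tc$animal, tc$session,
                    tc$ear, tc$frequency_khz, tc$level_db)
      utils::write.csv(ep$traces, file.path(tdir, fn), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a cohort dataset container
#'
#' Validates the container schema and reconstructs the cohort as a lazy
#' handle: design, config and ground truth are loaded eagerly; traces are
#' re-synthesized on demand through [cohort_abr_epochs()] /
#' [cohort_startle_session()] (the container stores the generating config
#' and seed, which determine every trace bit-identically).
#'
#' @param dir Container directory written by [write_dataset()].
#' @return A `noise_cohort` object.
#' @export
read_dataset <- function(dir) {
  required <- c("meta.json", "config.json", "design.csv", "truth.json")
  missing <- required[!file.exists(file.path(dir, required))]
  if (length(missing)) {
    stop("invalid dataset container: missing member(s) ",
         paste(missing, collapse = ", "))
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  if (!identical(meta$schema_version, DATASET_SCHEMA_VERSION)) {
    stop(sprintf("dataset schema version mismatch: container %s, reader %s",
                 meta$schema_version, DATASET_SCHEMA_VERSION))
  }
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(cohort_config, cfg[setdiff(names(cfg), character(0))])
  cohort <- make_cohort(config)
  # Cross-check the regenerated design against the stored one
  stored <- utils::read.csv(file.path(dir, "design.csv"),
                            stringsAsFactors = FALSE)
  if (!identical(stored$animal, cohort$animals$animal) ||
      !identical(stored$group, cohort$animals$group)) {
    stop("dataset container is inconsistent with its config: ",
         "design.csv does not match the regenerated cohort")
  }
  cohort
}
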