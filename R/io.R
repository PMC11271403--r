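#' Write a cohort to plain-text files
#'
#' Profiles go to `profiles.csv`; all streams are stacked into a single
#' long-format `streams.csv` with columns `patient_id`, `timestamp`
#' (ISO-8601 UTC), `channel`, `value`.
#'
#' @param cohort A list with `profiles` and `streams` (see
#'   [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pf <- file.path(dir, "profiles.csv")
  sf <- file.path(dir, "streams.csv")
  utils::write.csv(cohort$profiles, pf, row.names = FALSE)
  streams <- do.call(rbind, cohort$streams)
  streams$timestamp <- format(streams$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  utils::write.csv(streams, sf, row.names = FALSE)
  invisible(c(profiles = pf, streams = sf))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `profiles.csv` and `streams.csv`.
#' @return A list with `profiles` and a named list of per-patient `streams`.
#' @export
read_cohort <- function(dir) {
  profiles <- utils::read.csv(file.path(dir, "profiles.csv"),
                              stringsAsFactors = FALSE)
  profiles$nyha_baseline <- factor(profiles$nyha_baseline,
                                   levels = c("II", "III", "IV"))
  profiles$nyha_final <- factor(profiles$nyha_final,
                                levels = c("I", "II", "III", "IV"))
  long <- utils::read.csv(file.path(dir, "streams.csv"),
                          stringsAsFactors = FALSE)
  long$timestamp <- as.POSIXct(long$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC")
  streams <- split(long, long$patient_id)
  streams <- lapply(streams, function(d) {
    rownames(d) <- NULL
    d
  })
  list(profiles = profiles, streams = streams[profiles$patient_id])
}

#' Write patient embeddings to CSV
#' @param embeddings Data frame from [ssl_oof_embeddings()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_embeddings <- function(embeddings, path) {
  utils::write.csv(embeddings, path, row.names = FALSE)
  invisible(path)
}
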