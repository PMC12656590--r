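# Plain-text serialization: CSV for samples/features/reports, JSON sidecars
# for metadata. Small volumes; diffable artifacts ease debugging and testing.

#' Write one recording as CSV + JSON sidecar
#'
#' @param rec A recording (see [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(rec$participant_id, ".csv"))
  js <- file.path(dir, paste0(rec$participant_id, ".json"))
  df <- data.frame(sample_index = seq_along(rec$channels[[1]]) - 1)
  for (pl in names(rec$channels))
    df[[tolower(pl)]] <- as.integer(rec$channels[[pl]])
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(list(participant_id = rec$participant_id,
                            label = rec$label, fs = rec$fs),
                       js, auto_unbox = TRUE)
  invisible(c(csv = csv, json = js))
}

#' Read a recording written by [write_recording()]
#'
#' @param dir Directory holding the pair of files.
#' @param participant_id Participant id (file stem).
#' @return A recording list.
#' @export
read_recording <- function(dir, participant_id) {
  meta <- jsonlite::read_json(file.path(dir, paste0(participant_id,
                                                    ".json")))
  df <- utils::read.csv(file.path(dir, paste0(participant_id, ".csv")))
  chan_cols <- setdiff(names(df), "sample_index")
  channels <- lapply(chan_cols, function(cc) as.numeric(df[[cc]]))
  names(channels) <- toupper(chan_cols)
  list(participant_id = meta$participant_id, label = meta$label,
       fs = as.numeric(meta$fs), channels = channels)
}

#' Write a cohort (per-participant files plus a manifest)
#'
#' @param cohort List of recordings.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort) write_recording(rec, dir)
  manifest <- data.frame(
    participant_id = vapply(cohort, `[[`, character(1), "participant_id"),
    label = vapply(cohort, `[[`, character(1), "label"),
    fs = vapply(cohort, `[[`, numeric(1), "fs")
  )
  path <- file.path(dir, "cohort.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List of recordings.
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "cohort.csv"))
  lapply(manifest$participant_id, function(id) read_recording(dir, id))
}

#' Write a block feature table as CSV
#'
#' One row per block: identity columns, inclusion flag, then feature_0..;
#' excluded blocks carry NA features.
#'
#' @param feats A [bin_features()] result (or `meta`+`x` pair).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(feats, path) {
  df <- cbind(feats$meta[, c("participant_id", "placement", "start_sample",
                             "label", "included")],
              as.data.frame(feats$x))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature CSV written by [write_features_csv()]
#'
#' @param path CSV path.
#' @return List with `meta` and `x`.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- c("participant_id", "placement", "start_sample", "label",
                 "included")
  list(meta = df[, meta_cols],
       x = as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]))
}

#' Serialize an evaluation report (or list of them) to JSON
#'
#' @param x `eval_report`, or any list of plain values.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run manifest for reproducibility audits
#'
#' Records the master seed, the configuration, package and R versions, and
#' md5 digests of the artifacts a run produced; two runs with the same seed
#' and configuration yield identical digests.
#'
#' @param seed Master seed of the run.
#' @param config Configuration list.
#' @param files Character vector of artifact paths to digest.
#' @return Manifest list.
#' @export
run_manifest <- function(seed, config, files = character(0)) {
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  list(seed = seed, config = config,
       package_version = as.character(utils::packageVersion("bcgaf")),
       r_version = R.version.string,
       timestamp = format(Sys.time(), tz = "UTC"),
       file_md5 = digests)
}
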