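# Plain-text interchange: CSV for recordings and quaternion streams, JSON
# for cohort manifests and split indices. Real recordings with the same
# schema can enter the pipeline through these readers.

#' Write / read a single-channel recording as CSV
#'
#' Two columns, `t` (seconds) and `value`; metadata travels in a JSON
#' sidecar (`<path>.meta.json`).
#'
#' @param rec A `signal_recording`.
#' @param path Output CSV path.
#' @return `write_recording_csv`: the path, invisibly. `read_recording_csv`:
#'   a `signal_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "signal_recording"))
  n <- length(rec$samples)
  utils::write.csv(data.frame(t = (seq_len(n) - 1) / rec$fs,
                              value = rec$samples),
                   path, row.names = FALSE)
  meta <- list(fs = rec$fs, modality = rec$modality, channel = rec$channel,
               subject_id = rec$subject_id, design_label = rec$design_label,
               trial = rec$trial)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    meta <- list(fs = 1 / stats::median(diff(df$t)), modality = "emg-raw",
                 channel = "wrist", subject_id = NA, design_label = NA,
                 trial = 1L)
  }
  signal_recording(df$value, fs = meta$fs, modality = meta$modality,
                   channel = meta$channel, subject_id = meta$subject_id,
                   design_label = meta$design_label, trial = meta$trial)
}

#' Write / read a paired quaternion stream as CSV
#'
#' Columns `t`, then `hand_qw, hand_qx, hand_qy, hand_qz` and
#' `forearm_qw, ..., forearm_qz`; metadata in a JSON sidecar.
#'
#' @param qs A `quaternion_stream`.
#' @param path Output CSV path.
#' @return The path invisibly, or the reconstructed `quaternion_stream`.
#' @export
write_quaternions_csv <- function(qs, path) {
  stopifnot(inherits(qs, "quaternion_stream"))
  n <- nrow(qs$hand_q)
  df <- data.frame((seq_len(n) - 1) / qs$fs, qs$hand_q, qs$forearm_q)
  names(df) <- c("t", paste0("hand_q", c("w", "x", "y", "z")),
                 paste0("forearm_q", c("w", "x", "y", "z")))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(fs = qs$fs, subject_id = qs$subject_id,
                            design_label = qs$design_label, trial = qs$trial),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_quaternions_csv
#' @export
read_quaternions_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(fs = 1 / stats::median(diff(df$t)), subject_id = NA,
         design_label = NA, trial = 1L)
  }
  structure(list(
    hand_q = as.matrix(df[, paste0("hand_q", c("w", "x", "y", "z"))]),
    forearm_q = as.matrix(df[, paste0("forearm_q", c("w", "x", "y", "z"))]),
    fs = meta$fs, subject_id = meta$subject_id, trial = meta$trial,
    design_label = meta$design_label, params = NULL),
    class = "quaternion_stream")
}

#' Write a cohort manifest as JSON
#'
#' @param cohort A `tremor_cohort`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "tremor_cohort"))
  jsonlite::write_json(list(config = unclass(cohort$config),
                            manifest = cohort$manifest),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write split indices as JSON
#'
#' Persists the partition index lists so the same split can be reused
#' across model families and sessions.
#'
#' @param splits Named list of integer index vectors from [split_windows()].
#' @param path Output JSON path.
#' @return The path invisibly; `read_split_json` returns the list.
#' @export
write_split_json <- function(splits, path) {
  jsonlite::write_json(splits, path)
  invisible(path)
}

#' @rdname write_split_json
#' @export
read_split_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE), as.integer)
}
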