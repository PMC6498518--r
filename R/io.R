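# Plain-text interchange: TSV matrices and tables, JSON sidecars. All
# artifacts are UTF-8 tab-delimited with header rows; matrices carry channel
# labels in the header and first column so write -> read round-trips are
# lossless for every field consumed downstream.

#' Write / read a labeled square matrix as TSV
#'
#' @param m matrix with row/column labels
#' @param path output file
#' @return `write_matrix_tsv()`: the path, invisibly. `read_matrix_tsv()`:
#'   the labeled matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m) %||% paste0("V", seq_len(nrow(m))),
                   unclass(m), check.names = FALSE)
  names(df)[-1] <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a connectivity matrix with a JSON provenance sidecar
#'
#' Writes `<path>` (TSV, labels in header and first column) and
#' `<path>.json` (band, condition, subject, estimator, observation count).
#'
#' @param conn a `connectivity_matrix`
#' @param path output TSV path
#' @return the path, invisibly
#' @export
write_connectivity_tsv <- function(conn, path) {
  write_matrix_tsv(conn, path)
  meta <- list(band = attr(conn, "band"), condition = attr(conn, "condition"),
               subject_id = attr(conn, "subject_id"),
               estimator = attr(conn, "estimator"),
               n_obs = attr(conn, "n_obs"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Write an EEG recording as a delimited channels-x-samples matrix
#'
#' One row per channel, channel label in the first column, tab-delimited.
#'
#' @param rec an [eeg_recording()]
#' @param path output TSV path
#' @return the path, invisibly
#' @export
write_recording_tsv <- function(rec, path) {
  df <- data.frame(channel = rec$channel_labels, rec$data,
                   check.names = FALSE)
  names(df)[-1] <- paste0("s", seq_len(ncol(rec$data)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @param fs sampling rate of the stored recording (Hz)
#' @param subject_id,condition metadata to attach
#' @export
read_recording_tsv <- function(path, fs, subject_id = NA_character_,
                               condition = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE)
  data <- as.matrix(df[, -1, drop = FALSE])
  dimnames(data) <- NULL
  eeg_recording(data, fs, df[[1]], subject_id = subject_id,
                condition = condition)
}

#' Export a synthetic cohort to plain-text files
#'
#' Writes per-subject behavioral tables (pitch trials, AQ responses, PIS
#' answers: TSV, one row per trial / item / tone), optionally the EEG
#' matrices (one TSV per subject x condition; these are large), and a JSON
#' sidecar `ground_truth.json` with the generating configuration.
#'
#' @param cohort a `cohort`
#' @param dir output directory (created if needed)
#' @param include_eeg also write EEG matrices (default `FALSE`)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir, include_eeg = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(pitch_trials = "pitch_trials.tsv",
               aq_responses = "aq_responses.tsv",
               pis_answers = "pis_answers.tsv")
  for (nm in names(tabs)) {
    rows <- do.call(rbind, lapply(cohort$subjects, function(s) {
      cbind(subject_id = s$subject_id, group = s$group, s[[nm]])
    }))
    utils::write.table(rows, file.path(dir, tabs[[nm]]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  subj <- do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group,
               starting_age = s$starting_age)
  }))
  utils::write.table(subj, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (include_eeg) {
    for (s in cohort$subjects) {
      for (cond in names(s$recordings)) {
        rec <- materialize_recording(s$recordings[[cond]])
        write_recording_tsv(rec, file.path(dir,
          sprintf("eeg_%s_%s.tsv", s$subject_id, cond)))
      }
    }
  }
  cfg <- cohort$config
  gt <- list(
    n_per_group = as.list(cfg$n_per_group), fs = cfg$fs,
    duration_s = cfg$duration_s, conditions = cfg$conditions,
    montage = cfg$montage, noise_exponent = cfg$noise_exponent,
    seed = cfg$seed,
    behavior_params = cfg$behavior_params,
    couplings_per_group = lapply(cfg$couplings_per_group, function(cl) {
      lapply(cl, function(cp) list(channel_pair = cp$channel_pair,
                                   band = cp$band, phase_lag = cp$phase_lag,
                                   strength = cp$strength))
    }))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
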