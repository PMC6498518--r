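# Recording containers, epoching and band definitions.

#' EEG recording container
#'
#' A multichannel resting-state EEG recording: a channels x samples numeric
#' matrix with ordered unique channel labels, a sampling rate, and condition /
#' subject metadata.
#'
#' @param data channels x samples numeric matrix (no NaN/Inf)
#' @param fs sampling rate in Hz
#' @param channel_labels character vector, one unique label per row of `data`
#' @param subject_id subject identifier
#' @param condition recording condition, typically `"EO"` (eyes open) or
#'   `"EC"` (eyes closed)
#' @return an object of class `eeg_recording`
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          subject_id = NA_character_, condition = NA_character_) {
  stopifnot_finite_matrix(data, "EEG data")
  if (fs <= 0) stop("fs must be positive")
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels must match the number of data rows")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(data) <- channel_labels
  structure(
    list(subject_id = subject_id, condition = condition, fs = fs,
         channel_labels = channel_labels, data = data),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject=%s condition=%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Segment a recording into non-overlapping epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' `epoch_length_s` seconds; a trailing partial segment is discarded. A 300-s
#' recording yields 75 four-second epochs.
#'
#' @param rec an [eeg_recording()]
#' @param epoch_length_s epoch length in seconds (default 4)
#' @return an object of class `epoched_data` with fields `data` (an
#'   epochs x channels x samples array), `fs`, `epoch_length_s`,
#'   `channel_labels` and `dropped` (provenance of removed epochs)
#' @export
segment_epochs <- function(rec, epoch_length_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"), epoch_length_s > 0)
  spe <- round(rec$fs * epoch_length_s)
  n_samples <- ncol(rec$data)
  n_epochs <- floor(n_samples / spe)
  if (n_epochs < 1) {
    stop(sprintf("recording (%.2f s) is shorter than one epoch (%g s)",
                 n_samples / rec$fs, epoch_length_s))
  }
  arr <- array(NA_real_, dim = c(n_epochs, nrow(rec$data), spe))
  for (e in seq_len(n_epochs)) {
    arr[e, , ] <- rec$data[, ((e - 1) * spe + 1):(e * spe), drop = FALSE]
  }
  structure(
    list(data = arr, fs = rec$fs, epoch_length_s = epoch_length_s,
         channel_labels = rec$channel_labels,
         subject_id = rec$subject_id, condition = rec$condition,
         dropped = integer(0)),
    class = "epoched_data"
  )
}

#' @export
print.epoched_data <- function(x, ...) {
  cat(sprintf("<epoched_data> %d epochs x %d channels x %d samples (%g s @ %g Hz); %d dropped\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$epoch_length_s, x$fs, length(x$dropped)))
  invisible(x)
}

#' Remove epochs (artifact-rejection hook)
#'
#' Drops the epochs at `indices` (indices into the current epoch sequence) and
#' records them in the `dropped` provenance field. Mirrors manual removal of
#' residual-artifact epochs; at least one epoch must remain.
#'
#' @param epoched an `epoched_data` object
#' @param indices integer indices of epochs to remove (may be empty)
#' @return the reduced `epoched_data`
#' @export
drop_epochs <- function(epoched, indices) {
  stopifnot(inherits(epoched, "epoched_data"))
  indices <- unique(as.integer(indices))
  if (length(indices) == 0) return(epoched)
  n <- dim(epoched$data)[1]
  if (any(indices < 1 | indices > n)) stop("epoch indices out of range")
  if (length(indices) >= n) stop("cannot drop all epochs")
  epoched$dropped <- c(epoched$dropped, indices)
  epoched$data <- epoched$data[-indices, , , drop = FALSE]
  epoched
}

#' Frequency-band specification
#'
#' @param name band name
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`
#' @param taper `"hanning"` (single taper) or `"dpss"` (multitaper)
#' @param smoothing_hz spectral smoothing half-bandwidth W in Hz; required for
#'   (and only for) `taper = "dpss"`
#' @return an object of class `band_spec`
#' @export
band_spec <- function(name, f_lo, f_hi, taper = c("hanning", "dpss"),
                      smoothing_hz = NULL) {
  taper <- match.arg(taper)
  stopifnot(f_lo > 0, f_hi > f_lo)
  if (taper == "dpss" && is.null(smoothing_hz)) {
    stop("dpss taper requires smoothing_hz")
  }
  if (taper == "hanning" && !is.null(smoothing_hz)) {
    stop("smoothing_hz only applies to dpss tapering")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi, taper = taper,
                 smoothing_hz = smoothing_hz),
            class = "band_spec")
}

#' Canonical band presets
#'
#' The five analysis bands — delta 2-4, theta 4-7, alpha 7-13, beta 13-30 and
#' gamma 30-60 Hz — with Hanning tapering for delta/theta and DPSS multitaper
#' smoothing of +/- 1, 2 and 4 Hz for alpha, beta and gamma. A `beta_low`
#' preset (13-18 Hz, W = 2 Hz) is also provided: group results in this
#' literature are frequently reported on the lower beta range while methods
#' sections define beta as 13-30 Hz, and the two conventions are not
#' interchangeable.
#'
#' @param names optional character vector selecting a subset of presets
#' @return a named list of [band_spec()] objects
#' @export
band_presets <- function(names = NULL) {
  all <- list(
    delta    = band_spec("delta", 2, 4, "hanning"),
    theta    = band_spec("theta", 4, 7, "hanning"),
    alpha    = band_spec("alpha", 7, 13, "dpss", smoothing_hz = 1),
    beta     = band_spec("beta", 13, 30, "dpss", smoothing_hz = 2),
    beta_low = band_spec("beta_low", 13, 18, "dpss", smoothing_hz = 2),
    gamma    = band_spec("gamma", 30, 60, "dpss", smoothing_hz = 4)
  )
  if (is.null(names)) return(all)
  missing <- setdiff(names, names(all))
  if (length(missing)) stop("unknown band preset(s): ", paste(missing, collapse = ", "))
  all[names]
}
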