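# Taper construction for the multitaper cross-spectral estimator.
#
# Delta and theta use a single Hanning window; alpha, beta and gamma use
# discrete prolate spheroidal sequences (DPSS, Slepian sequences) with
# half-bandwidth smoothing W of 1, 2 and 4 Hz. No installed package provides
# DPSS, so they are computed here from the classical symmetric tridiagonal
# eigenproblem whose eigenvectors are the Slepian sequences; the K most
# concentrated tapers correspond to the K largest eigenvalues.

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the `k` most spectrally concentrated orthonormal tapers of length
#' `n` for normalized half-bandwidth `w` (cycles per sample), via the
#' tridiagonal matrix whose eigenvectors are the DPSS. Results are cached per
#' `(n, w, k)` since the eigendecomposition is the dominant cost.
#'
#' @param n taper length in samples
#' @param w normalized half-bandwidth, `W_hz / fs`, in (0, 0.5)
#' @param k number of tapers to return
#' @return an `n x k` matrix of orthonormal tapers (unit energy columns)
#' @export
dpss_tapers <- function(n, w, k) {
  stopifnot(n >= 2, w > 0, w < 0.5, k >= 1, k <= n)
  key <- sprintf("n%d_w%.10g_k%d", n, w, k)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  t_idx <- 0:(n - 1)
  diag_v <- ((n - 1) / 2 - t_idx)^2 * cos(2 * pi * w)
  off_v <- t_idx[-1] * (n - t_idx[-1]) / 2
  m <- matrix(0, n, n)
  diag(m) <- diag_v
  m[cbind(seq_len(n - 1), 2:n)] <- off_v
  m[cbind(2:n, seq_len(n - 1))] <- off_v
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  # fix arbitrary eigenvector signs: symmetric tapers positive mean,
  # antisymmetric tapers positive initial slope
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (tap[2, j] < tap[1, j]) {
      tap[, j] <- -tap[, j]
    }
  }
  .taper_cache[[key]] <- tap
  tap
}

#' Hanning window of unit energy
#' @param n window length in samples
#' @return numeric vector of length `n` scaled to unit sum of squares
#' @export
hanning_taper <- function(n) {
  stopifnot(n >= 2)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  h / sqrt(sum(h^2))
}

# Number of DPSS tapers for epoch length T seconds and half-bandwidth W Hz:
# the standard 2 N W - 1 rule with time-bandwidth product NW = T * W.
n_dpss_tapers <- function(epoch_length_s, smoothing_hz) {
  max(1L, as.integer(round(2 * epoch_length_s * smoothing_hz - 1)))
}

# Taper matrix (samples x tapers) for a band specification.
band_tapers <- function(band, n_samples, fs, epoch_length_s) {
  if (band$taper == "hanning") {
    matrix(hanning_taper(n_samples), ncol = 1)
  } else {
    k <- n_dpss_tapers(epoch_length_s, band$smoothing_hz)
    dpss_tapers(n_samples, band$smoothing_hz / fs, k)
  }
}
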