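# Multitaper cross-spectra and phase-lag-index family connectivity estimators.
#
# For each epoch (and each DPSS taper where the band uses multitapering) the
# demeaned, tapered FFT is computed per channel; every frequency bin inside the
# band contributes one complex cross-spectral observation
# S_xyt = X_x(f) conj(X_y(f)) per channel pair. PLI is the absolute mean sign
# of imag(S_xyt); wPLI weights each sign by |imag(S_xyt)|:
#   wPLI_xy = |sum_t imag(S_xyt)| / sum_t |imag(S_xyt)|
# Both pool all epoch x taper x in-band-bin observations into a single ratio
# per pair (a per-bin-averaged variant is available via `pooling`).
#
# Because both estimators depend on the observations only through per-bin sums
# of sign(imag), imag and |imag|, cross_spectra() accumulates those exact
# sufficient statistics by default; the raw complex observations (which for a
# 300-s 28-channel gamma recording would occupy gigabytes) are kept only on
# request.

#' Per-band multitaper cross-spectral observations
#'
#' @param epoched an `epoched_data` object (see [segment_epochs()])
#' @param band a [band_spec()]
#' @param keep `"sufficient"` (default) stores exact per-bin sufficient
#'   statistics for PLI/wPLI; `"observations"` additionally retains the full
#'   complex observation matrix (observations x pairs) for diagnostics and
#'   small-sample work
#' @return an object of class `cross_spectral_obs`
#' @export
cross_spectra <- function(epoched, band, keep = c("sufficient", "observations")) {
  stopifnot(inherits(epoched, "epoched_data"), inherits(band, "band_spec"))
  keep <- match.arg(keep)
  fs <- epoched$fs
  if (band$f_hi >= fs / 2) {
    stop(sprintf("band %s (up to %g Hz) exceeds the Nyquist frequency %g Hz",
                 band$name, band$f_hi, fs / 2))
  }
  n_epochs <- dim(epoched$data)[1]
  n_chan <- dim(epoched$data)[2]
  spe <- dim(epoched$data)[3]
  if (n_epochs < 1) stop("no epochs to analyze")
  if (n_chan < 2) stop("connectivity requires at least 2 channels")

  freqs <- (0:(spe - 1)) * fs / spe
  bins <- which(freqs >= band$f_lo & freqs <= band$f_hi)
  if (length(bins) == 0) {
    stop(sprintf("band %s contains no FFT bins at resolution %g Hz",
                 band$name, fs / spe))
  }
  nb <- length(bins)
  tap <- band_tapers(band, spe, fs, epoched$epoch_length_s)
  n_tapers <- ncol(tap)

  pr <- upper_pairs(n_chan)
  pi_ <- pr[, 1]
  pj_ <- pr[, 2]
  np <- nrow(pr)

  sum_sign <- matrix(0, nb, np)
  sum_imag <- matrix(0, nb, np)
  sum_abs <- matrix(0, nb, np)
  obs <- if (keep == "observations") {
    matrix(complex(real = 0), n_epochs * n_tapers * nb, np)
  } else NULL

  # All tapers of one epoch share a single batched FFT whose columns are
  # taper-major: column (k-1)*n_chan + ch holds taper k applied to channel ch.
  tap_cols <- tap[, rep(seq_len(n_tapers), each = n_chan), drop = FALSE]
  ch_rep <- rep(seq_len(n_chan), n_tapers)
  if (!is.null(obs)) {
    # flat FFT indices laying observations out as (taper-block of bins) x pair
    f_rep <- rep(rep(seq_len(nb), n_tapers), np)
    k_off <- rep(rep((seq_len(n_tapers) - 1L) * n_chan, each = nb), np)
    idx_i <- (k_off + rep(pi_, each = nb * n_tapers) - 1L) * nb + f_rep
    idx_j <- (k_off + rep(pj_, each = nb * n_tapers) - 1L) * nb + f_rep
  }

  row0 <- 0L
  for (e in seq_len(n_epochs)) {
    x <- t(matrix(epoched$data[e, , ], nrow = n_chan)) # samples x channels
    x <- sweep(x, 2, colMeans(x))                      # per-epoch detrend (mean)
    xf <- stats::mvfft(x[, ch_rep, drop = FALSE] * tap_cols)[bins, , drop = FALSE]
    accum_cross_spectra(xf, pi_, pj_, n_chan, sum_sign, sum_imag, sum_abs)
    if (!is.null(obs)) {
      a <- as.numeric(Re(xf)); b <- as.numeric(Im(xf))
      res <- a[idx_i] * a[idx_j] + b[idx_i] * b[idx_j]
      ims <- b[idx_i] * a[idx_j] - a[idx_i] * b[idx_j]
      obs[row0 + seq_len(nb * n_tapers), ] <- complex(real = res, imaginary = ims)
      row0 <- row0 + nb * n_tapers
    }
  }

  structure(
    list(band = band, fs = fs, channel_labels = epoched$channel_labels,
         subject_id = epoched$subject_id, condition = epoched$condition,
         pairs = pr, freqs = freqs[bins],
         n_epochs = n_epochs, n_tapers = n_tapers, n_bins = nb,
         n_obs = n_epochs * n_tapers * nb,
         store = keep,
         suff = list(sum_sign = sum_sign, sum_imag = sum_imag,
                     sum_abs = sum_abs, n_per_bin = n_epochs * n_tapers),
         obs = obs),
    class = "cross_spectral_obs"
  )
}

#' @export
print.cross_spectral_obs <- function(x, ...) {
  cat(sprintf("<cross_spectral_obs> band %s (%g-%g Hz): %d pairs, %d epochs x %d tapers x %d bins = %d observations [%s]\n",
              x$band$name, x$band$f_lo, x$band$f_hi, nrow(x$pairs),
              x$n_epochs, x$n_tapers, x$n_bins, x$n_obs, x$store))
  invisible(x)
}

new_connectivity_matrix <- function(values, obs, estimator) {
  n <- length(obs$channel_labels)
  m <- sym_from_upper(values, n, obs$channel_labels)
  structure(m, class = c("connectivity_matrix", "matrix"),
            band = obs$band$name, condition = obs$condition,
            subject_id = obs$subject_id, estimator = estimator,
            n_obs = obs$n_obs)
}

#' Phase lag index
#'
#' `PLI_xy = | mean_t sgn(imag(S_xyt)) |`, with `sgn(0) = 0`. Values lie in
#' `[0, 1]`; 0 means symmetric (or zero/pi-lag) phase-difference
#' distributions, 1 a constant-sign phase lead/lag.
#'
#' @param obs a `cross_spectral_obs` object
#' @return a symmetric `connectivity_matrix` with zero diagonal
#' @export
pli <- function(obs) {
  stopifnot(inherits(obs, "cross_spectral_obs"))
  if (obs$n_obs < 1) stop("empty observation set")
  v <- abs(colSums(obs$suff$sum_sign) / obs$n_obs)
  new_connectivity_matrix(v, obs, "pli")
}

#' Weighted phase lag index
#'
#' `wPLI_xy = | sum_t imag(S_xyt) | / sum_t |imag(S_xyt)|`, defined as 0 when
#' the denominator vanishes (identical or exactly zero/pi-lagged channels,
#' which the estimator deliberately ignores as volume-conduction-like).
#'
#' @param obs a `cross_spectral_obs` object
#' @param pooling `"pooled"` (default) forms one ratio over all epoch x taper
#'   x bin observations; `"per_bin"` computes a wPLI per frequency bin and
#'   averages across in-band bins
#' @return a symmetric `connectivity_matrix` with zero diagonal, values in
#'   `[0, 1]`
#' @export
wpli <- function(obs, pooling = c("pooled", "per_bin")) {
  stopifnot(inherits(obs, "cross_spectral_obs"))
  pooling <- match.arg(pooling)
  if (obs$n_obs < 1) stop("empty observation set")
  if (pooling == "pooled") {
    num <- abs(colSums(obs$suff$sum_imag))
    den <- colSums(obs$suff$sum_abs)
    v <- ifelse(den > 0, num / den, 0)
  } else {
    wb <- ifelse(obs$suff$sum_abs > 0, abs(obs$suff$sum_imag) / obs$suff$sum_abs, 0)
    v <- colMeans(wb)
  }
  new_connectivity_matrix(v, obs, "wpli")
}

#' One-step band connectivity from epoched data
#'
#' Convenience wrapper: [cross_spectra()] followed by [wpli()] or [pli()].
#'
#' @inheritParams cross_spectra
#' @param estimator `"wpli"` or `"pli"`
#' @param pooling passed to [wpli()]
#' @return a `connectivity_matrix`
#' @export
band_connectivity <- function(epoched, band, estimator = c("wpli", "pli"),
                              pooling = "pooled") {
  estimator <- match.arg(estimator)
  cs <- cross_spectra(epoched, band)
  if (estimator == "wpli") wpli(cs, pooling = pooling) else pli(cs)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, band %s, condition %s, subject %s: %d x %d, n_obs %d\n",
              attr(x, "estimator"), attr(x, "band"), attr(x, "condition"),
              attr(x, "subject_id"), nrow(x), ncol(x), attr(x, "n_obs")))
  cat(sprintf("  off-diagonal range [%.4f, %.4f]\n",
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}
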