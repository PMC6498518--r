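make_rec <- function(data, fs = 128, labels = NULL) {
  labels <- labels %||% paste0("ch", seq_len(nrow(data)))
  eeg_recording(data, fs, labels, subject_id = "t", condition = "EC")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("epoch segmentation follows the non-overlapping 4-s scheme", {
  rec <- simulate_recording(montage = c("A", "B"), fs = 512, duration_s = 300,
                            seed = 1)
  ep <- segment_epochs(rec)
  expect_equal(dim(ep$data), c(75, 2, 2048))
  # trailing partial segment is discarded
  rec7 <- simulate_recording(montage = c("A", "B"), fs = 128, duration_s = 7,
                             seed = 1)
  expect_equal(dim(segment_epochs(rec7)$data)[1], 1)
  rec3 <- simulate_recording(montage = c("A", "B"), fs = 128, duration_s = 3,
                             seed = 1)
  expect_error(segment_epochs(rec3), "shorter than one epoch")
  # epochs tile the recording in temporal order
  expect_equal(unname(ep$data[2, 1, 1]), unname(rec$data[1, 2049]))
})

test_that("epoch dropping records provenance and refuses to empty the data", {
  rec <- simulate_recording(montage = c("A", "B"), fs = 128, duration_s = 40,
                            seed = 2)
  ep <- segment_epochs(rec)
  expect_identical(drop_epochs(ep, integer(0)), ep)
  ep2 <- drop_epochs(ep, c(1, 5, 7, 9, 10))
  expect_equal(dim(ep2$data)[1], 5)
  expect_equal(sort(ep2$dropped), c(1, 5, 7, 9, 10))
  expect_error(drop_epochs(ep, 1:10), "all epochs")
  expect_error(drop_epochs(ep, 99), "out of range")
})

test_that("band specifications and presets are validated", {
  expect_error(band_spec("x", 4, 2), "f_hi")
  expect_error(band_spec("x", 4, 8, "dpss"), "smoothing_hz")
  expect_error(band_spec("x", 4, 8, "hanning", smoothing_hz = 1), "dpss")
  bp <- band_presets()
  expect_equal(bp$delta$f_lo, 2); expect_equal(bp$delta$f_hi, 4)
  expect_equal(bp$gamma$f_hi, 60)
  expect_equal(bp$beta_low$f_hi, 18)
  expect_identical(bp$theta$taper, "hanning")
  expect_identical(bp$beta$taper, "dpss")
  expect_error(band_presets("nope"), "unknown")
})

test_that("multitaper scheme uses 2TW-1 DPSS tapers and in-band bins only", {
  rec <- simulate_recording(montage = c("A", "B"), fs = 128, duration_s = 20,
                            seed = 3)
  ep <- segment_epochs(rec)
  cs_beta <- cross_spectra(ep, band_presets()$beta)   # T = 4 s, W = 2 Hz
  expect_equal(cs_beta$n_tapers, 15)                  # 2*4*2 - 1
  cs_alpha <- cross_spectra(ep, band_presets()$alpha) # W = 1 Hz
  expect_equal(cs_alpha$n_tapers, 7)
  cs_theta <- cross_spectra(ep, band_presets()$theta) # Hanning
  expect_equal(cs_theta$n_tapers, 1)
  expect_true(all(cs_beta$freqs >= 13 & cs_beta$freqs <= 30))
  expect_equal(cs_beta$n_obs,
               dim(ep$data)[1] * cs_beta$n_tapers * cs_beta$n_bins)
  expect_error(cross_spectra(ep, band_spec("hi", 50, 70, "dpss", 4)),
               "Nyquist")
})

test_that("dpss tapers are orthonormal and spectrally concentrated", {
  tap <- dpss_tapers(256, 2 / 128, 15)
  expect_equal(crossprod(tap), diag(15), tolerance = 1e-8)
  # first taper concentrates essentially all energy inside +-W
  pad <- 8
  xf <- stats::fft(c(tap[, 1], rep(0, (pad - 1) * 256)))
  f <- (seq_along(xf) - 1) / (pad * 256)
  inband <- f <= 2 / 128 | f >= 1 - 2 / 128
  expect_gt(sum(Mod(xf[inband])^2) / sum(Mod(xf)^2), 0.999)
})

test_that("cross-spectral phase follows the configured lag", {
  # single 4-s epoch, sinusoid at an exact theta bin, second channel delayed
  fs <- 128
  tvec <- (0:511) / fs
  f0 <- 5                       # 5 Hz, bin center, inside theta 4-7
  tau <- 0.01                   # 10 ms delay -> phase 2 pi f0 tau
  x <- cos(2 * pi * f0 * tvec)
  y <- cos(2 * pi * f0 * (tvec - tau))
  rec <- make_rec(rbind(x, y), fs = fs)
  cs <- cross_spectra(segment_epochs(rec), band_presets()$theta,
                      keep = "observations")
  bin <- which(cs$freqs == f0)
  ph <- Arg(cs$obs[bin, 1])
  expect_equal(ph, 2 * pi * f0 * tau, tolerance = 1e-3)
})

test_that("spectral energy of a pure tone lands in its own band", {
  fs <- 128
  tvec <- (0:(40 * fs - 1)) / fs
  x <- cos(2 * pi * 10 * tvec)            # 10 Hz: alpha
  y <- cos(2 * pi * 10 * tvec + pi / 3)
  rec <- make_rec(rbind(x, y), fs = fs)
  ep <- segment_epochs(rec)
  cs_a <- cross_spectra(ep, band_presets()$alpha, keep = "observations")
  cs_b <- cross_spectra(ep, band_presets()$beta, keep = "observations")
  # >= 99% of the cross-spectral energy over both bands falls in alpha
  pa <- sum(Mod(cs_a$obs)); pb <- sum(Mod(cs_b$obs))
  expect_gt(pa / (pa + pb), 0.99)
})

test_that("PLI and wPLI match hand-evaluated fixtures", {
  # imag parts {1, 2, -1}: PLI = |(1+1-1)/3| = 1/3, wPLI = |1+2-1|/(1+2+1) = 0.5
  fx <- obs_fixture(c(1, 2, -1))
  expect_equal(pli(fx)["A", "B"], 1 / 3)
  expect_equal(wpli(fx)["A", "B"], 0.5)
  # constant sign: both reach 1
  fx1 <- obs_fixture(c(0.2, 5, 0.01))
  expect_equal(pli(fx1)["A", "B"], 1)
  expect_equal(wpli(fx1)["A", "B"], 1)
  # perfectly symmetric signs: PLI 0
  expect_equal(pli(obs_fixture(c(0.7, -0.7)))["A", "B"], 0)
  # all-zero imaginary parts: wPLI defined as 0 by the 0/0 convention
  expect_equal(wpli(obs_fixture(c(0, 0, 0)))["A", "B"], 0)
})

test_that("zero-lag identical signals give zero wPLI", {
  x <- stats::rnorm(128 * 16)
  rec <- make_rec(rbind(x, x))
  w <- wpli(cross_spectra(segment_epochs(rec), band_presets()$theta))
  expect_equal(w["ch1", "ch2"], 0)
})

test_that("estimators obey the matrix contract and invariances", {
  rec <- simulate_recording(montage = default_montage()[1:5], fs = 128,
                            duration_s = 20, seed = 8)
  ep <- segment_epochs(rec)
  cs <- cross_spectra(ep, band_presets()$alpha)
  for (m in list(pli(cs), wpli(cs))) {
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unclass(m), t(unclass(m)))
    expect_true(all(diag(m) == 0))
  }
  # invariance to positive rescaling of the signals
  rec2 <- rec
  rec2$data <- rec2$data * 3.7
  w2 <- wpli(cross_spectra(segment_epochs(rec2), band_presets()$alpha))
  expect_equal(unclass(w2), unclass(wpli(cs)), tolerance = 1e-12)
  # relabeling x <-> y permutes the matrix accordingly
  recp <- rec
  perm <- c(2, 1, 3, 5, 4)
  recp$data <- rec$data[perm, ]
  recp$channel_labels <- rec$channel_labels[perm]
  rownames(recp$data) <- recp$channel_labels
  wp <- wpli(cross_spectra(segment_epochs(recp), band_presets()$alpha))
  w <- wpli(cs)
  expect_equal(unclass(wp[rec$channel_labels, rec$channel_labels]),
               unclass(w), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sufficient-statistics and full-observation stores agree", {
  cp <- list(coupling_spec(c("Fp1", "F4"), "beta", pi / 3, 1))
  rec <- simulate_recording(montage = default_montage()[1:4], fs = 128,
                            duration_s = 16, couplings = cp, seed = 12)
  ep <- segment_epochs(rec)
  for (band in band_presets(c("theta", "beta"))) {
    cs_s <- cross_spectra(ep, band)
    cs_o <- cross_spectra(ep, band, keep = "observations")
    expect_equal(unclass(wpli(cs_s)), unclass(wpli(cs_o)), tolerance = 1e-12)
    expect_equal(unclass(pli(cs_s)), unclass(pli(cs_o)), tolerance = 1e-12)
    # direct transcription of the estimator definitions on the raw
    # observations reproduces the matrices
    im <- Im(cs_o$obs)
    man_w <- abs(colSums(im)) / colSums(abs(im))
    man_p <- abs(colSums(sign(im))) / nrow(im)
    w <- wpli(cs_o); p <- pli(cs_o)
    expect_equal(unname(w[upper.tri(w)]), unname(man_w), tolerance = 1e-12)
    expect_equal(unname(p[upper.tri(p)]), unname(man_p), tolerance = 1e-12)
  }
})

test_that("per-bin pooling variant is a valid estimator", {
  rec <- simulate_recording(montage = default_montage()[1:4], fs = 128,
                            duration_s = 20, seed = 13)
  cs <- cross_spectra(segment_epochs(rec), band_presets()$beta)
  w_pb <- wpli(cs, pooling = "per_bin")
  expect_true(all(w_pb >= 0 & w_pb <= 1))
  expect_equal(unclass(w_pb), t(unclass(w_pb)))
  # single-bin band: per-bin and pooled coincide
  bs <- band_spec("one", 5, 5.1, "hanning")
  cs1 <- cross_spectra(segment_epochs(rec), bs)
  expect_equal(cs1$n_bins, 1)
  expect_equal(unclass(wpli(cs1, pooling = "per_bin")),
               unclass(wpli(cs1, pooling = "pooled")), tolerance = 1e-12)
})
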