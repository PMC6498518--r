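# Synthetic cohort generation: resting-state EEG with known phase-coupling
# ground truth, pitch-adjustment trials, AQ item responses and tone-naming
# screening. Everything is deterministic under (config, seed).
#
# EEG model: each channel is independent 1/f^exponent noise (unit RMS); each
# coupling adds a shared band-limited Gaussian oscillation (an independent
# random process per coupling, so distinct couplings are mutually incoherent)
# to both channels, the second channel's copy phase-delayed by phase_lag
# radians at every in-band frequency via the analytic signal. Nonzero, non-pi
# phase lags make the imaginary cross-spectrum nondegenerate, which is exactly
# what the wPLI estimator detects; zero/pi lags are invisible to it by
# construction.

#' Default 28-channel scalp montage
#'
#' Standard extended 10-20 positions for a 28-electrode resting-state setup.
#' @return character vector of channel labels
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "FC3", "FC4", "C3", "C4", "CP3", "CP4",
    "P3", "P4", "F7", "F8", "FT7", "FT8", "T7", "T8", "TP7", "TP8",
    "P7", "P8", "O1", "O2", "Oz", "Fz", "Cz", "Pz")
}

#' Phase-coupling specification
#'
#' Declares a band-limited phase-lagged coupling between two channels of the
#' synthetic montage. Zero and pi lags are rejected when `strength > 0`
#' because the wPLI estimator is blind to them, so such a spec could never be
#' recovered downstream.
#'
#' @param channel_pair character vector of two distinct channel labels
#' @param band band name (must match a generated band, e.g. `"beta"`)
#' @param phase_lag phase delay of the second channel in radians, in
#'   `(-pi, pi]`; must differ from 0 and pi when `strength > 0`
#' @param strength amplitude of the coupled component relative to the noise
#'   RMS (>= 0)
#' @return an object of class `coupling_spec`
#' @export
coupling_spec <- function(channel_pair, band, phase_lag, strength = 1) {
  stopifnot(length(channel_pair) == 2, strength >= 0)
  if (channel_pair[1] == channel_pair[2]) stop("channel labels must be distinct")
  if (phase_lag <= -pi || phase_lag > pi) stop("phase_lag must lie in (-pi, pi]")
  if (strength > 0 && (phase_lag == 0 || phase_lag == pi)) {
    stop("phase_lag 0 or pi is invisible to wPLI; use a strictly intermediate lag")
  }
  structure(list(channel_pair = channel_pair, band = band,
                 phase_lag = phase_lag, strength = strength),
            class = "coupling_spec")
}

# 1/f^exponent noise of length n, unit RMS, via spectral shaping of white noise
pink_noise <- function(n, exponent = 1) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- seq_len(n) - 1
  f <- pmin(f, n - f)           # two-sided frequency index
  scale <- c(0, f[-1]^(-exponent / 2))
  y <- Re(stats::fft(xf * scale, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Analytic band-limited Gaussian noise: complex signal whose spectrum lives
# on the positive frequencies inside [f_lo, f_hi]; Re(z) is the carrier,
# Re(z * exp(-i phi)) the same carrier delayed by phi radians at every
# in-band frequency. Scaled so the real part has unit RMS.
analytic_band_noise <- function(n, fs, f_lo, f_hi) {
  w <- stats::rnorm(n)
  wf <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= f_lo & f <= f_hi & f <= fs / 2
  wf[!keep] <- 0
  z <- stats::fft(wf, inverse = TRUE) / n
  s <- stats::sd(Re(z))
  if (s == 0) stop("band contains no spectral support at this length")
  z / s
}

#' Simulate a multichannel resting-state EEG recording
#'
#' Independent `1/f^exponent` background noise per channel (unit RMS) plus,
#' for each [coupling_spec()], a shared band-limited Gaussian oscillation
#' spanning the coupling's band with the configured amplitude; the second
#' channel's copy is phase-delayed by `phase_lag` radians at every in-band
#' frequency (analytic-signal phase shift). Couplings use independent
#' carrier processes, so two couplings that do not share a channel stay
#' mutually incoherent — the recovered wPLI topology is exactly the
#' configured one.
#'
#' @param montage ordered channel labels
#' @param fs sampling rate in Hz; must exceed twice the highest coupled band
#'   edge
#' @param duration_s recording duration in seconds
#' @param couplings list of [coupling_spec()] objects (possibly empty)
#' @param noise_exponent spectral slope of the background noise (default 1)
#' @param seed integer seed
#' @param bands band definitions used to resolve coupling band names
#'   (default [band_presets()])
#' @param subject_id,condition metadata attached to the recording
#' @return an [eeg_recording()] of dimensions `length(montage) x
#'   round(fs * duration_s)`
#' @export
simulate_recording <- function(montage = default_montage(), fs = 512,
                               duration_s = 300, couplings = list(),
                               noise_exponent = 1, seed = 1L,
                               bands = band_presets(),
                               subject_id = NA_character_,
                               condition = NA_character_) {
  stopifnot(duration_s > 0, fs > 0)
  n <- round(fs * duration_s)
  n_chan <- length(montage)
  for (cp in couplings) {
    if (!all(cp$channel_pair %in% montage)) {
      stop("coupling references unknown channel label(s): ",
           paste(setdiff(cp$channel_pair, montage), collapse = ", "))
    }
    if (is.null(bands[[cp$band]])) stop("unknown coupling band: ", cp$band)
    if (bands[[cp$band]]$f_hi >= fs / 2) {
      stop(sprintf("coupled band %s exceeds Nyquist (fs = %g)", cp$band, fs))
    }
  }
  data <- with_seed(seed, {
    d <- matrix(0, n_chan, n)
    for (ch in seq_len(n_chan)) d[ch, ] <- pink_noise(n, noise_exponent)
    for (ci in seq_along(couplings)) {
      cp <- couplings[[ci]]
      if (cp$strength == 0) next
      bd <- bands[[cp$band]]
      z <- analytic_band_noise(n, fs, bd$f_lo, bd$f_hi)
      i1 <- match(cp$channel_pair[1], montage)
      i2 <- match(cp$channel_pair[2], montage)
      d[i1, ] <- d[i1, ] + cp$strength * Re(z)
      d[i2, ] <- d[i2, ] + cp$strength * Re(z * exp(-1i * cp$phase_lag))
    }
    d
  })
  eeg_recording(data, fs, montage, subject_id = subject_id,
                condition = condition)
}

#' Simulate pitch-adjustment trials
#'
#' Targets cycle through the 12 pitch classes, three occurrences each per
#' block of 36, in a block-wise shuffled order. The final frequency is the
#' target pitch class at a uniformly chosen octave within the adjustable
#' 220-880 Hz range, displaced by `epsilon` cents with
#' `epsilon ~ Normal(bias_cents, sigma_cents^2)`. Start frequencies are drawn
#' uniformly on 220-880 Hz in 1-Hz steps (recorded, not used in scoring).
#'
#' @param n_trials number of trials (default 108 = 3 blocks of 36)
#' @param sigma_cents SD of the cents deviation (>= 0)
#' @param bias_cents mean cents deviation
#' @param seed integer seed
#' @return data frame with columns `trial`, `block`, `target_pitch_class`,
#'   `start_freq_hz`, `final_freq_hz`
#' @export
simulate_pitch_trials <- function(n_trials = 108, sigma_cents = 50,
                                  bias_cents = 0, seed = 1L) {
  stopifnot(n_trials > 0, sigma_cents >= 0)
  classes <- pitch_class_names()
  with_seed(seed, {
    n_blocks <- ceiling(n_trials / 36)
    targets <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(classes, 3))  # 3 x 12 notes per block, shuffled
    }))[seq_len(n_trials)]
    blocks <- rep(seq_len(n_blocks), each = 36)[seq_len(n_trials)]
    start <- sample(220:880, n_trials, replace = TRUE)
    final <- vapply(seq_len(n_trials), function(i) {
      s <- pitch_class_semitone(targets[i])
      base <- 440 * 2^((s - 9) / 12)
      octs <- -4:4
      freqs <- base * 2^octs
      ok <- freqs >= 220 & freqs <= 880
      f0 <- sample(rep(freqs[ok], 2), 1)  # rep() guards length-1 sample()
      eps <- stats::rnorm(1, bias_cents, sigma_cents)
      f0 * 2^(eps / 1200)
    }, numeric(1))
    data.frame(trial = seq_len(n_trials), block = blocks,
               target_pitch_class = targets, start_freq_hz = start,
               final_freq_hz = final)
  })
}

#' Default synthetic AQ item bank
#'
#' 50 items, 5 subscales of 10 each, alternate items reverse-keyed (25 of 50),
#' matching the instrument's structure without reproducing item text.
#' @return data frame with columns `item`, `subscale`, `reverse`
#' @export
aq_item_key <- function() {
  subscales <- c("social_skills", "attention_switching", "attention_to_detail",
                 "communication", "imagination")
  data.frame(item = 1:50,
             subscale = rep(subscales, each = 10),
             reverse = rep(c(FALSE, TRUE), 25))
}

#' Simulate AQ questionnaire responses
#'
#' Each item is endorsed in the autistic direction with probability
#' `plogis(trait_theta)`; the 4-level agreement response respects the item's
#' keying direction (reverse-keyed items express endorsement as disagreement).
#'
#' @param trait_theta latent trait on the logit scale (0 gives an expected
#'   total of 25/50)
#' @param item_key item bank (default [aq_item_key()]); must cover 50 items
#' @param seed integer seed
#' @return data frame with columns `item`, `response` (1 = definitely
#'   disagree ... 4 = definitely agree)
#' @export
simulate_aq_responses <- function(trait_theta, item_key = aq_item_key(),
                                  seed = 1L) {
  if (nrow(item_key) != 50 || !all(1:50 %in% item_key$item)) {
    stop("item_key must cover items 1..50")
  }
  with_seed(seed, {
    endorsed <- stats::rbinom(50, 1, stats::plogis(trait_theta)) == 1
    # agreement side: endorse straight-keyed items by agreeing,
    # reverse-keyed items by disagreeing
    agree <- ifelse(item_key$reverse, !endorsed, endorsed)
    response <- ifelse(agree, sample(3:4, 50, replace = TRUE),
                       sample(1:2, 50, replace = TRUE))
    data.frame(item = item_key$item, response = response)
  })
}

#' Cohort configuration
#'
#' Defaults mirror the study conditions: 31 + 33 subjects, 28-channel montage,
#' 512 Hz, 300-s recordings in both eyes-open and eyes-closed conditions.
#' Behavioral defaults per group: an absolute-pitch-like group with tightly
#' tuned adjustments (sigma 52 cents, so MAD ~ 41 cents via the half-normal
#' mean) and elevated autistic traits, and a relative-pitch-like group whose
#' large sigma (600 cents) wraps to a near-uniform cents distribution
#' (MAD ~ 300 cents), matching what untrained absolute judgement produces.
#'
#' @param n_per_group named integer vector of group sizes (>= 2 each)
#' @param montage ordered unique channel labels
#' @param fs sampling rate in Hz
#' @param duration_s recording duration per condition in seconds
#' @param conditions subset of `c("EO", "EC")`
#' @param couplings_per_group named list (one entry per group) of lists of
#'   [coupling_spec()]
#' @param behavior_params named list per group with elements `sigma_cents`,
#'   `bias_cents`, `aq_theta` (location), `aq_theta_sd`, `start_age_mean`,
#'   `start_age_sd`, `pis_p_correct`
#' @param noise_exponent background-noise spectral slope
#' @param seed master integer seed
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_per_group = c(AP = 31, RP = 33),
                          montage = default_montage(),
                          fs = 512, duration_s = 300,
                          conditions = c("EO", "EC"),
                          couplings_per_group = default_couplings(names(n_per_group)),
                          behavior_params = default_behavior_params(names(n_per_group)),
                          noise_exponent = 1,
                          seed = 1L) {
  stopifnot(all(n_per_group >= 2), length(n_per_group) >= 1)
  if (is.null(names(n_per_group))) stop("n_per_group must be named by group")
  if (anyDuplicated(montage)) stop("montage labels must be unique")
  if (duration_s < 4) stop("duration_s must cover at least one 4-s epoch")
  if (!all(conditions %in% c("EO", "EC")) || length(conditions) < 1) {
    stop("conditions must be a non-empty subset of c('EO', 'EC')")
  }
  groups <- names(n_per_group)
  if (!all(groups %in% names(couplings_per_group))) {
    stop("couplings_per_group must have one entry per group")
  }
  if (!all(groups %in% names(behavior_params))) {
    stop("behavior_params must have one entry per group")
  }
  for (g in groups) {
    for (cp in couplings_per_group[[g]]) {
      bad <- setdiff(cp$channel_pair, montage)
      if (length(bad)) {
        stop("coupling for group ", g, " references channel(s) not in the montage: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  structure(list(n_per_group = n_per_group, montage = montage, fs = fs,
                 duration_s = duration_s, conditions = conditions,
                 couplings_per_group = couplings_per_group,
                 behavior_params = behavior_params,
                 noise_exponent = noise_exponent, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default group coupling structure
#'
#' Both groups carry one shared alpha coupling (no group difference). In the
#' beta band the first group's couplings close triangles among six
#' fronto-temporal channels (high transitivity) while the second group has
#' the same number of couplings arranged as a chain over the same channels
#' (low transitivity) — a known ground-truth clustering difference restricted
#' to beta.
#'
#' @param groups character vector of group names (first = triangle-rich)
#' @return named list of coupling lists
#' @export
default_couplings <- function(groups = c("AP", "RP")) {
  stopifnot(length(groups) >= 1)
  chans <- c("F7", "FT7", "T7", "F8", "FT8", "T8")
  shared <- list(coupling_spec(c("O1", "O2"), "alpha", pi / 3, 1))
  tri_edges <- list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))
  chain_edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1))
  mk <- function(edges) lapply(edges, function(e) {
    coupling_spec(chans[e], "beta", pi / 4, 1.2)
  })
  out <- list()
  out[[groups[1]]] <- c(shared, mk(tri_edges))
  for (g in groups[-1]) out[[g]] <- c(shared, mk(chain_edges))
  out
}

#' Default per-group behavioral parameters
#' @param groups character vector of group names (first = absolute-pitch-like)
#' @return named list of parameter lists
#' @export
default_behavior_params <- function(groups = c("AP", "RP")) {
  ap <- list(sigma_cents = 52, bias_cents = 0, aq_theta = stats::qlogis(20.5 / 50),
             aq_theta_sd = 0.4, start_age_mean = 6.0, start_age_sd = 3.0,
             pis_p_correct = 0.79)
  rp <- list(sigma_cents = 600, bias_cents = 0, aq_theta = stats::qlogis(16.9 / 50),
             aq_theta_sd = 0.4, start_age_mean = 7.1, start_age_sd = 2.2,
             pis_p_correct = 0.15)
  out <- list()
  out[[groups[1]]] <- ap
  for (g in groups[-1]) out[[g]] <- rp
  out
}

#' Generate a synthetic cohort
#'
#' Produces, per subject: seeded EEG recording references for every configured
#' condition (materialized on demand by [get_recording()] so that full-length
#' cohorts do not have to reside in memory), pitch-adjustment trials, AQ item
#' responses, 36 tone-naming answers and a starting age. Identical
#' (config, seed) yields a bit-identical cohort.
#'
#' @param config a [cohort_config()]
#' @return an object of class `cohort`: list with `config` and `subjects`
#'   (each with `subject_id`, `group`, `recordings`, `pitch_trials`,
#'   `aq_responses`, `pis_answers`, `starting_age`)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- list()
  sid <- 0L
  for (g in names(config$n_per_group)) {
    bp <- config$behavior_params[[g]]
    for (i in seq_len(config$n_per_group[[g]])) {
      sid <- sid + 1L
      id <- sprintf("S%03d", sid)
      recs <- lapply(stats::setNames(config$conditions, config$conditions),
                     function(cond) {
        structure(list(montage = config$montage, fs = config$fs,
                       duration_s = config$duration_s,
                       couplings = config$couplings_per_group[[g]],
                       noise_exponent = config$noise_exponent,
                       seed = derive_seed(config$seed, "eeg", id, cond),
                       subject_id = id, condition = cond),
                  class = "recording_ref")
      })
      theta <- with_seed(derive_seed(config$seed, "theta", id),
                         stats::rnorm(1, bp$aq_theta, bp$aq_theta_sd))
      age <- with_seed(derive_seed(config$seed, "age", id),
                       max(1, stats::rnorm(1, bp$start_age_mean, bp$start_age_sd)))
      pis <- simulate_pis_answers(bp$pis_p_correct,
                                  seed = derive_seed(config$seed, "pis", id))
      subjects[[sid]] <- list(
        subject_id = id, group = g,
        recordings = recs,
        pitch_trials = simulate_pitch_trials(
          108, bp$sigma_cents, bp$bias_cents,
          seed = derive_seed(config$seed, "pat", id)),
        aq_responses = simulate_aq_responses(
          theta, seed = derive_seed(config$seed, "aq", id)),
        pis_answers = pis,
        starting_age = age)
    }
  }
  structure(list(config = config, subjects = subjects), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf("<cohort> %d subjects (%s); conditions %s; %d-channel montage @ %g Hz, %g s\n",
              length(x$subjects),
              paste(sprintf("%s n=%d", names(table(groups)), table(groups)),
                    collapse = ", "),
              paste(x$config$conditions, collapse = "/"),
              length(x$config$montage), x$config$fs, x$config$duration_s))
  invisible(x)
}

# 36-tone naming answers with per-tone probability p of a correct label
simulate_pis_answers <- function(p_correct, seed = 1L) {
  classes <- pitch_class_names()
  with_seed(seed, {
    key <- sample(rep(classes, 3))
    correct <- stats::runif(36) < p_correct
    answer <- vapply(seq_len(36), function(i) {
      if (correct[i]) key[i] else sample(setdiff(classes, key[i]), 1)
    }, character(1))
    data.frame(tone = 1:36, correct_pitch_class = key, answer = answer)
  })
}

#' Materialize a subject's EEG recording
#'
#' Cohorts store seeded recording references; this synthesizes the actual
#' time series deterministically.
#'
#' @param cohort a `cohort`
#' @param subject_id subject identifier
#' @param condition condition label
#' @return an [eeg_recording()]
#' @export
get_recording <- function(cohort, subject_id, condition) {
  stopifnot(inherits(cohort, "cohort"))
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  s <- cohort$subjects[[match(subject_id, ids)]]
  if (is.null(s)) stop("unknown subject: ", subject_id)
  ref <- s$recordings[[condition]]
  if (is.null(ref)) stop("condition not present: ", condition)
  materialize_recording(ref)
}

#' @rdname get_recording
#' @param ref a `recording_ref` stored inside a cohort
#' @export
materialize_recording <- function(ref) {
  stopifnot(inherits(ref, "recording_ref"))
  simulate_recording(montage = ref$montage, fs = ref$fs,
                     duration_s = ref$duration_s, couplings = ref$couplings,
                     noise_exponent = ref$noise_exponent, seed = ref$seed,
                     subject_id = ref$subject_id, condition = ref$condition)
}
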