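test_that("cents mapping uses octave equivalence and A440 equal temperament", {
  expect_equal(cents_to_nearest_target(440, "A"), 0)
  expect_equal(cents_to_nearest_target(880, "A"), 0)
  expect_equal(cents_to_nearest_target(220, "A"), 0)
  # A#4 = 466.1638 Hz is +100 cents from A
  expect_equal(cents_to_nearest_target(440 * 2^(1 / 12), "A"), 100,
               tolerance = 1e-9)
  expect_equal(cents_to_nearest_target(466.164, "A"), 100, tolerance = 1e-2)
  # enharmonic and composite labels
  expect_equal(cents_to_nearest_target(440 * 2^(-3 / 12), "F#/Gb"), 0,
               tolerance = 1e-9)
  expect_equal(pitch_class_semitone("Gb"), pitch_class_semitone("F#"))
  # exact tritone maps to the half-open lower bound
  expect_equal(cents_to_nearest_target(440 * 2^0.5, "A"), -600,
               tolerance = 1e-9)
  expect_error(cents_to_nearest_target(-10, "A"), "positive")
  expect_error(pitch_class_semitone("H"), "unknown")
})

test_that("MAD and SDfoM follow their definitions", {
  expect_equal(pitch_mad(c(0, 0, 0)), 0)
  expect_equal(pitch_mad(c(10, -20, 30)), 20)
  expect_equal(sdfom(c(10, -20, 30)), 10)  # sd of |C| = {10, 20, 30}
  expect_equal(sdfom(c(5, 5, -5)), 0)
  # sign flips never matter
  set.seed(2)
  d <- stats::rnorm(50, 0, 80)
  flip <- d * sample(c(-1, 1), 50, replace = TRUE)
  expect_equal(pitch_mad(flip), pitch_mad(d))
  expect_equal(sdfom(flip), sdfom(d))
  # scale behavior
  expect_equal(pitch_mad(3 * d), 3 * pitch_mad(d))
  expect_equal(sdfom(3 * d), 3 * sdfom(d))
  # two-pass textbook SD oracle
  expect_equal(sdfom(d), sqrt(sum((abs(d) - mean(abs(d)))^2) / 49),
               tolerance = 1e-12)
  expect_error(pitch_mad(numeric(0)), "at least one")
  expect_error(sdfom(5), "at least two")
})

test_that("octave transposition of final frequencies leaves scores unchanged", {
  tr <- simulate_pitch_trials(n_trials = 36, sigma_cents = 60, seed = 6)
  d1 <- cents_deviations(tr)
  tr2 <- tr
  tr2$final_freq_hz <- tr2$final_freq_hz * 2
  d2 <- cents_deviations(tr2)
  expect_equal(pitch_mad(d2), pitch_mad(d1), tolerance = 1e-9)
  expect_equal(sdfom(d2), sdfom(d1), tolerance = 1e-9)
})

test_that("z-standardization is anchored to the reference group", {
  # published summary fixture: MAD 41.37 against reference 296.84 +- 86.12
  # (three-point reference {m - s, m, m + s} has mean m and SD s exactly)
  ref_m <- c(296.84 - 86.12, 296.84, 296.84 + 86.12)
  ref_s <- c(329.77 - 122.77, 329.77, 329.77 + 122.77)
  z <- z_scores(41.37, 52.31, ref_m, ref_s)
  expect_equal(z$z_mad, (41.37 - 296.84) / 86.12, tolerance = 1e-12)
  expect_equal(z$z_mad, -2.967, tolerance = 1e-3)
  # subject at the reference mean scores zero
  expect_equal(z_scores(10, 5, c(8, 12), c(4, 6))$z_mad, 0)
  # standardizing the reference group itself: mean 0, SD 1
  set.seed(3)
  mads <- stats::rnorm(20, 300, 80); sds <- stats::rnorm(20, 320, 100)
  zz <- z_scores(mads, sds, mads, sds)
  expect_equal(mean(zz$z_mad), 0, tolerance = 1e-12)
  expect_equal(stats::sd(zz$z_mad), 1, tolerance = 1e-12)
  expect_error(z_scores(1, 1, c(2, 2), c(1, 2)), "zero variance")
  expect_error(z_scores(1, 1, 5, c(1, 2)), "at least two")
})

test_that("AQ scoring honors keying direction and bounds", {
  key <- aq_item_key()
  # all responses maximally agreeing: only straight-keyed items score
  all_agree <- data.frame(item = 1:50, response = 4)
  expect_equal(score_aq(all_agree, key)$total, sum(!key$reverse))
  # fully autistic-direction protocol scores 50, fully opposite 0
  autistic <- data.frame(item = 1:50, response = ifelse(key$reverse, 1, 4))
  expect_equal(score_aq(autistic, key)$total, 50)
  opposite <- data.frame(item = 1:50, response = ifelse(key$reverse, 4, 1))
  expect_equal(score_aq(opposite, key)$total, 0)
  # subscales partition the total
  sc <- score_aq(autistic, key)
  expect_equal(sum(unlist(sc$subscales)), sc$total)
  expect_equal(length(sc$subscales), 5)
  # brute-force recount oracle on a random protocol
  set.seed(9)
  resp <- data.frame(item = 1:50, response = sample(1:4, 50, replace = TRUE))
  manual <- 0
  for (i in 1:50) {
    agree <- resp$response[i] >= 3
    if ((key$reverse[i] && !agree) || (!key$reverse[i] && agree)) {
      manual <- manual + 1
    }
  }
  expect_equal(score_aq(resp, key)$total, manual)
  # missing handling
  expect_error(score_aq(resp[-5, ], key), "missing")
  pro <- score_aq(resp[-(1:5), ], key, missing = "prorate")
  expect_equal(pro$total, sum_points <- score_aq(
    data.frame(item = 6:50, response = resp$response[6:50]),
    key, missing = "prorate")$total)
})

test_that("PIS scoring and the 12/36 group rule behave at the boundary", {
  key <- rep(pitch_class_names(), 3)
  all_right <- key
  expect_equal(score_pis(all_right, key), 36)
  # enharmonic spelling counts as correct
  ans <- key; ans[key == "F#"] <- "Gb"
  expect_equal(score_pis(ans, key), 36)
  # exactly 13 correct: first 13 match, the rest shifted by a semitone
  classes <- pitch_class_names()
  shift <- classes[(match(key, classes) %% 12) + 1]
  ans13 <- c(key[1:13], shift[14:36])
  expect_equal(score_pis(ans13, key), 13)
  expect_error(score_pis(key[1:35], key), "36")
  expect_identical(assign_group(13), "AP")
  expect_identical(assign_group(12), "RP")
  expect_identical(assign_group(36), "AP")
  ov <- assign_group(21, override = "RP")
  expect_identical(as.character(ov), "RP")
  expect_true(attr(ov, "override"))
  expect_identical(attr(ov, "pis_based"), "AP")
})

test_that("cohort scoring recovers the generating group structure", {
  cc <- cohort_config(n_per_group = c(AP = 6, RP = 6),
                      montage = default_montage()[1:4],
                      fs = 128, duration_s = 8, conditions = "EC",
                      couplings_per_group = list(AP = list(), RP = list()),
                      seed = 23)
  scores <- score_cohort(generate_cohort(cc))
  expect_equal(nrow(scores), 12)
  ap <- scores$group == "AP"
  # AP-like group: tight adjustments, near-uniform RP deviations around 300
  expect_lt(mean(scores$mad[ap]), 100)
  expect_gt(mean(scores$mad[!ap]), 200)
  # z-scores referenced to RP: RP mean 0 by construction
  expect_equal(mean(scores$z_mad[!ap]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(scores$z_mad[!ap]), 1, tolerance = 1e-9)
  # PIS rule reproduces group membership for clearly separated groups
  expect_true(all(scores$group_by_rule[ap] == "AP"))
  expect_true(all(scores$group_by_rule[!ap] == "RP"))
  # half-normal recovery at the configured sigma
  expect_equal(mean(scores$mad[ap]), 52 * sqrt(2 / pi), tolerance = 6)
})
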