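# Behavioral scoring: pitch-adjustment accuracy (MAD) and consistency
# (SDfoM), z-standardization against the non-AP reference group, AQ
# questionnaire scoring, tone-naming (PIS) scoring and group assignment.

#' Pitch-class utilities
#'
#' The 12 equal-tempered pitch classes, A4 = 440 Hz reference. Enharmonic
#' spellings (Db = C#, "F#/Gb" composites) are equated.
#' @return `pitch_class_names()`: character vector of the 12 canonical names.
#' @export
pitch_class_names <- function() {
  c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
}

#' @rdname pitch_class_names
#' @param label a pitch-class label, e.g. `"A"`, `"Gb"`, `"F#/Gb"`
#' @return `pitch_class_semitone()`: semitone index 0-11 (C = 0)
#' @export
pitch_class_semitone <- function(label) {
  map <- c(C = 0, "B#" = 0, "C#" = 1, Db = 1, D = 2, "D#" = 3, Eb = 3,
           E = 4, Fb = 4, F = 5, "E#" = 5, "F#" = 6, Gb = 6, G = 7,
           "G#" = 8, Ab = 8, A = 9, "A#" = 10, Bb = 10, B = 11, Cb = 11)
  first <- strsplit(trimws(label), "/")[[1]][1]
  s <- map[first]
  if (is.na(s)) stop("unknown pitch class label: ", label)
  unname(s)
}

#' Signed cents deviation to the nearest octave-equivalent target
#'
#' The final frequency is compared to the octave-equivalent instance of the
#' target pitch class nearest to it (within 6 semitones / 600 cents), in
#' A4 = 440 Hz equal temperament. The result lies in `[-600, 600)`; the
#' half-open upper bound resolves the exact-tritone tie deterministically.
#'
#' @param final_freq frequency in Hz (> 0); vectorized
#' @param target_pitch_class target note label (octave-free)
#' @return signed deviation in cents
#' @export
cents_to_nearest_target <- function(final_freq, target_pitch_class) {
  if (any(final_freq <= 0)) stop("frequencies must be positive")
  s <- pitch_class_semitone(target_pitch_class)
  ref <- 440 * 2^((s - 9) / 12)
  d <- 1200 * log2(final_freq / ref)
  ((d + 600) %% 1200) - 600
}

#' Mean absolute deviation of pitch adjustments
#'
#' `MAD = sum(|C_i|) / N`: the mean absolute cents deviation over trials —
#' pitch-adjustment accuracy (lower is better).
#'
#' @param deviations signed cents deviations `C_i`
#' @return MAD in cents
#' @export
pitch_mad <- function(deviations) {
  if (length(deviations) < 1) stop("at least one deviation required")
  mean(abs(deviations))
}

#' Standard deviation of absolute deviations (SDfoM)
#'
#' Sample standard deviation (divisor N-1) of the absolute cents deviations
#' around their mean (the MAD) — pitch-adjustment consistency, interpreted as
#' the tuning of the internal pitch template.
#'
#' @param deviations signed cents deviations `C_i`
#' @return SDfoM in cents
#' @export
sdfom <- function(deviations) {
  if (length(deviations) < 2) stop("at least two deviations required")
  stats::sd(abs(deviations))
}

#' Z-standardize MAD/SDfoM against a reference group
#'
#' `Z = (value - mean_ref) / SD_ref`, with the non-absolute-pitch group as
#' reference, so that absolute-pitch proficiency is expressed relative to the
#' unselected population.
#'
#' @param mad_value,sdfom_value a subject's MAD and SDfoM (cents)
#' @param ref_mads,ref_sdfoms MAD and SDfoM values of the reference group
#'   (>= 2 subjects each)
#' @return list with `z_mad` and `z_sdfom`
#' @export
z_scores <- function(mad_value, sdfom_value, ref_mads, ref_sdfoms) {
  if (length(ref_mads) < 2 || length(ref_sdfoms) < 2) {
    stop("reference group must contain at least two subjects")
  }
  sm <- stats::sd(ref_mads)
  ss <- stats::sd(ref_sdfoms)
  if (sm == 0 || ss == 0) stop("reference group has zero variance")
  list(z_mad = (mad_value - mean(ref_mads)) / sm,
       z_sdfom = (sdfom_value - mean(ref_sdfoms)) / ss)
}

#' Score an AQ questionnaire
#'
#' One point per item answered with mild or strong agreement in the keyed
#' autistic direction; reverse-keyed items score on disagreement. Responses
#' are on a 4-level agreement scale (1 = definitely disagree ... 4 =
#' definitely agree). The maximum total is 50.
#'
#' @param responses data frame with columns `item` and `response` (1-4)
#' @param item_key item bank with columns `item`, `subscale`, `reverse`
#'   (default [aq_item_key()])
#' @param missing `"error"` (default) rejects incomplete questionnaires;
#'   `"prorate"` scales the total from answered items
#' @return list with `total` and named `subscales`
#' @export
score_aq <- function(responses, item_key = aq_item_key(),
                     missing = c("error", "prorate")) {
  missing <- match.arg(missing)
  key <- item_key[order(item_key$item), ]
  merged <- merge(key, responses, by = "item", all.x = TRUE)
  if (any(is.na(merged$response))) {
    if (missing == "error") stop("missing AQ responses for item(s): ",
                                 paste(merged$item[is.na(merged$response)],
                                       collapse = ", "))
  }
  if (!all(merged$response[!is.na(merged$response)] %in% 1:4)) {
    stop("responses must be on the 4-level scale 1..4")
  }
  agree <- merged$response >= 3
  point <- ifelse(merged$reverse, !agree, agree)
  sub <- tapply(point, merged$subscale, function(p) sum(p, na.rm = TRUE))
  total <- sum(point, na.rm = TRUE)
  if (missing == "prorate") {
    answered <- sum(!is.na(point))
    if (answered == 0) stop("no answered items")
    total <- total * nrow(key) / answered
  }
  list(total = total, subscales = as.list(sub))
}

#' Score tone-naming answers (PIS)
#'
#' Counts exact pitch-class matches (octave-free, enharmonics equated)
#' against the answer key over the 36 presented tones.
#'
#' @param answers character vector of 36 pitch-class answers
#' @param key character vector of 36 correct pitch classes
#' @return integer count of correct namings (0-36)
#' @export
score_pis <- function(answers, key) {
  if (length(answers) != 36 || length(key) != 36) {
    stop("PIS requires exactly 36 answers and 36 key entries")
  }
  sum(vapply(seq_len(36), function(i) {
    pitch_class_semitone(answers[i]) == pitch_class_semitone(key[i])
  }, logical(1)))
}

#' Assign the absolute-pitch group
#'
#' AP if strictly more than 12 of 36 tones were named correctly, else RP. An
#' explicit per-subject `override` (e.g. after behavioral re-assessment)
#' takes precedence and is recorded in the `override` attribute.
#'
#' @param pis_correct number of correctly named tones (0-36)
#' @param override optional `"AP"` or `"RP"` forcing the assignment
#' @return `"AP"` or `"RP"`, with attribute `override = TRUE` when forced
#' @export
assign_group <- function(pis_correct, override = NULL) {
  stopifnot(pis_correct >= 0, pis_correct <= 36)
  if (!is.null(override)) {
    override <- match.arg(override, c("AP", "RP"))
    return(structure(override, override = TRUE,
                     pis_based = if (pis_correct > 12) "AP" else "RP"))
  }
  if (pis_correct > 12) "AP" else "RP"
}

#' Score a whole cohort's behavior
#'
#' Computes per-subject MAD, SDfoM, Z-scores (referenced to the stated
#' reference group), AQ total and subscales, PIS count, rule-based group and
#' starting age.
#'
#' @param cohort a `cohort` from [generate_cohort()]
#' @param reference_group group label used for z-standardization (default
#'   `"RP"`, the non-absolute-pitch group)
#' @return a data frame, one row per subject
#' @export
score_cohort <- function(cohort, reference_group = "RP") {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    dev <- cents_deviations(s$pitch_trials)
    aq <- score_aq(s$aq_responses)
    pisc <- score_pis(s$pis_answers$answer, s$pis_answers$correct_pitch_class)
    out <- data.frame(subject_id = s$subject_id, group = s$group,
                      mad = pitch_mad(dev), sdfom = sdfom(dev),
                      aq_total = aq$total,
                      pis_correct = pisc,
                      group_by_rule = assign_group(pisc),
                      starting_age = s$starting_age)
    for (sc in names(aq$subscales)) out[[paste0("aq_", sc)]] <- aq$subscales[[sc]]
    out
  })
  scores <- do.call(rbind, rows)
  ref <- scores[scores$group == reference_group, ]
  if (nrow(ref) >= 2) {
    z <- z_scores(scores$mad, scores$sdfom, ref$mad, ref$sdfom)
    scores$z_mad <- z$z_mad
    scores$z_sdfom <- z$z_sdfom
  } else {
    scores$z_mad <- NA_real_
    scores$z_sdfom <- NA_real_
  }
  scores
}

#' Signed cents deviations for a trial table
#' @param trials data frame with `target_pitch_class` and `final_freq_hz`
#' @return numeric vector of signed cents deviations
#' @export
cents_deviations <- function(trials) {
  vapply(seq_len(nrow(trials)), function(i) {
    cents_to_nearest_target(trials$final_freq_hz[i],
                            trials$target_pitch_class[i])
  }, numeric(1))
}
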