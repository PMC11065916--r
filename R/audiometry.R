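# Two-step two-tone screening audiometry and the pure-tone-audiometry
# (PTA) reference classification.
#
# Screen protocol, per ear: a 2 kHz tone at 42 dB HL is presented twice.
# Hearing it fewer than twice fails the ear outright (the 0.5 kHz tone is
# not administered). Otherwise a 0.5 kHz tone at 47 dB HL is presented
# twice; hearing it fewer than twice fails the ear. Only the
# heard-twice/heard-twice pattern passes. "Failed" flags moderate-or-worse
# hearing loss.

#' Presentation levels of the two screening tones (dB HL)
#' @return named numeric vector: `tone_2k` = 42, `tone_500` = 47.
#' @export
screen_tone_levels <- function() c(tone_2k = 42, tone_500 = 47)

.check_heard <- function(x, name) {
  if (!all(is.na(x) | x %in% 0:2)) {
    stop_arhl("'%s' must be 0, 1 or 2 perceived presentations", name)
  }
  as.integer(x)
}

#' Two-step decision for a single ear
#'
#' @param heard_2k integer vector: presentations of the 2 kHz 42 dB HL tone
#'   perceived, 0..2.
#' @param heard_500 integer vector: presentations of the 0.5 kHz 47 dB HL
#'   tone perceived, 0..2, or `NA` when the tone was not administered. It
#'   must be `NA` exactly when `heard_2k < 2`: the second tone is only
#'   played after the first is heard twice.
#' @return character vector, `"passed"` or `"failed"`.
#' @examples
#' two_step_ear(heard_2k = 2, heard_500 = 2)  # passed
#' two_step_ear(heard_2k = 1)                 # failed, tone 2 never played
#' two_step_ear(heard_2k = 2, heard_500 = 0)  # failed
#' @export
two_step_ear <- function(heard_2k, heard_500 = NA_integer_) {
  heard_2k <- .check_heard(heard_2k, "heard_2k")
  if (anyNA(heard_2k)) stop_arhl("'heard_2k' is required for every ear")
  heard_500 <- .check_heard(rep_len(heard_500, length(heard_2k)), "heard_500")
  if (any(heard_2k < 2L & !is.na(heard_500))) {
    stop_arhl("'heard_500' present although the 2 kHz step already failed (the 0.5 kHz tone is never administered then)")
  }
  if (any(heard_2k == 2L & is.na(heard_500))) {
    stop_arhl("'heard_500' missing although the 2 kHz step was passed")
  }
  ifelse(heard_2k < 2L, "failed", ifelse(heard_500 < 2L, "failed", "passed"))
}

#' Two-step decision for both ears with binaural combination
#'
#' Each ear is judged by [two_step_ear()]; the overall screen passes when
#' at least one ear passes. The reference standard is the better-ear PTA
#' average, so the screen targets the better ear: a single passing ear
#' rules out moderate-or-worse loss in that ear.
#'
#' @param heard_2k_left,heard_500_left,heard_2k_right,heard_500_right
#'   per-ear perceived-presentation counts as in [two_step_ear()].
#' @return data.frame with columns `left`, `right`, `overall`, each
#'   `"passed"`/`"failed"`.
#' @export
two_step_binaural <- function(heard_2k_left, heard_500_left,
                              heard_2k_right, heard_500_right) {
  left <- two_step_ear(heard_2k_left, heard_500_left)
  right <- two_step_ear(heard_2k_right, heard_500_right)
  overall <- ifelse(left == "passed" | right == "passed", "passed", "failed")
  data.frame(left = left, right = right, overall = overall)
}

#' Grade band labels in order of increasing loss
#' @return character vector of the six PTA grades.
#' @export
pta_grades <- function() {
  c("normal", "mild", "moderate", "moderately_severe", "severe", "profound")
}

#' CSV column names of the reference PTA thresholds
#' @return character vector `pta_left_500` .. `pta_right_4000`.
#' @export
pta_columns <- function() {
  paste0(rep(c("pta_left_", "pta_right_"), each = 4L),
         rep(c(500, 1000, 2000, 4000), 2L))
}

.grade_from_avg <- function(avg) {
  # band edges: normal <= 25 < mild <= 40 < moderate <= 55
  #   < moderately_severe <= 70 < severe <= 90 < profound.
  # Non-integer averages are compared unrounded; the integer gaps of the
  # conventional 26-40 / 41-55 bands are closed by extending each lower
  # band upward, which preserves the two binary cuts (> 25, > 40) exactly.
  cut(avg, breaks = c(-Inf, 25, 40, 55, 70, 90, Inf), labels = pta_grades(),
      right = TRUE)
}

#' Classify reference pure-tone thresholds
#'
#' Computes, per subject, the four-frequency (0.5/1/2/4 kHz) air-conduction
#' mean of each ear, takes the better (lower) ear as the reference value,
#' assigns the grade band, and sets the two binary reference targets:
#' `hearing_loss` (better-ear average > 25 dB HL) and `moderate_or_worse`
#' (> 40 dB HL).
#'
#' @param thresholds data.frame with the eight columns of [pta_columns()],
#'   each in dB HL within -10..120; one row per subject.
#' @return data.frame with columns `left_avg`, `right_avg`,
#'   `better_ear_avg`, `better_ear` (`"left"`/`"right"`, left on ties),
#'   `grade` (factor over [pta_grades()]), `hearing_loss` and
#'   `moderate_or_worse` (logical).
#' @examples
#' pta_classify(data.frame(
#'   pta_left_500 = 30, pta_left_1000 = 40,
#'   pta_left_2000 = 50, pta_left_4000 = 60,
#'   pta_right_500 = 60, pta_right_1000 = 60,
#'   pta_right_2000 = 70, pta_right_4000 = 80))
#' @export
pta_classify <- function(thresholds) {
  missing_c <- setdiff(pta_columns(), names(thresholds))
  if (length(missing_c)) {
    stop_arhl("missing PTA threshold column(s): %s",
              paste(missing_c, collapse = ", "))
  }
  m <- as.matrix(thresholds[pta_columns()])
  if (anyNA(m)) {
    stop_arhl("missing PTA threshold (row %d)",
              which(rowSums(is.na(m)) > 0)[1L])
  }
  if (any(m < -10 | m > 120)) {
    stop_arhl("PTA thresholds must lie in -10..120 dB HL")
  }
  left <- rowMeans(m[, grep("^pta_left_", colnames(m)), drop = FALSE])
  right <- rowMeans(m[, grep("^pta_right_", colnames(m)), drop = FALSE])
  better <- pmin(left, right)
  data.frame(
    left_avg = left, right_avg = right, better_ear_avg = better,
    better_ear = ifelse(left <= right, "left", "right"),
    grade = .grade_from_avg(better),
    hearing_loss = better > 25,
    moderate_or_worse = better > 40)
}
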