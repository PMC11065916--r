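# Triage: combine the three screening components into a screen call and a
# re-screening recommendation.
#
# The protocol states the two pure corner cases: all components negative
# (low risk, HHIE-s 0-8, audiometry passed) -> re-screen in 6 months; all
# components positive -> re-screen in 3 months. Mixed patterns follow the
# OR rule: any positive component makes the screen positive with the
# 3-month interval. An OR call is the only combination consistent with a
# validation that reports 100% sensitivity and 100% NPV, and it maximises
# sensitivity, which is the purpose of a community screen. A failed
# audiometry additionally triggers referral to the general practitioner,
# since it is the component that flags moderate-or-worse loss directly.

#' Combine component results into a screening conclusion
#'
#' @param risk_stratum character vector, `"low"`/`"high"` (from
#'   [stratify_risk()]).
#' @param hhie_abnormal logical vector: HHIE-s total >= 10.
#' @param audiometry_failed logical vector: overall two-step screen failed.
#' @return data.frame with the inputs plus `screen_positive` (logical),
#'   `rescreen_interval_months` (6 when negative, 3 when positive) and
#'   `refer_to_gp` (mirrors `audiometry_failed`).
#' @examples
#' conclude_screen("low", FALSE, FALSE)   # negative, 6-month interval
#' conclude_screen("high", TRUE, TRUE)    # positive, 3-month interval
#' @export
conclude_screen <- function(risk_stratum, hhie_abnormal, audiometry_failed) {
  if (!all(risk_stratum %in% c("low", "high"))) {
    stop_arhl("'risk_stratum' must be 'low' or 'high'")
  }
  check_flag(hhie_abnormal, "hhie_abnormal")
  check_flag(audiometry_failed, "audiometry_failed")
  n <- length(risk_stratum)
  if (length(hhie_abnormal) != n || length(audiometry_failed) != n) {
    stop_arhl("component result vectors must have equal length")
  }
  positive <- risk_stratum == "high" | hhie_abnormal | audiometry_failed
  data.frame(
    risk_stratum = risk_stratum,
    hhie_abnormal = hhie_abnormal,
    audiometry_failed = audiometry_failed,
    screen_positive = positive,
    rescreen_interval_months = ifelse(positive, 3L, 6L),
    refer_to_gp = audiometry_failed)
}

#' Extract the screen-positive calls from a conclusions table
#'
#' Order-preserving accessor used by the validation stage.
#'
#' @param conclusions data.frame with a `screen_positive` column (possibly
#'   zero rows).
#' @return logical vector, one element per row.
#' @export
screen_positive_batch <- function(conclusions) {
  if (!is.data.frame(conclusions) ||
      !"screen_positive" %in% names(conclusions)) {
    stop_arhl("'conclusions' must be a data.frame with a screen_positive column")
  }
  as.logical(conclusions$screen_positive)
}
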