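# The screening pipeline: subjects table in, per-subject conclusions out,
# plus validation against the PTA reference when it is present.

#' Run the full screen on a subjects table
#'
#' Derives risk factors, scores and stratifies, scores the HHIE-s, applies
#' the two-step audiometry decision tree to both ears, and triages.
#'
#' @param subjects data.frame with the [profile_columns()],
#'   [hhie_columns()] and tone-trial columns (`heard_2k_left`,
#'   `heard_500_left`, `heard_2k_right`, `heard_500_right`); one row per
#'   subject.
#' @param threshold operational risk-score threshold (default 4).
#' @param assume_absent passed to [derive_risk_factors()].
#' @return data.frame with one row per subject, in input order:
#'   `subject_id`, `risk_score`, `risk_stratum`, `hhie_total`,
#'   `hhie_category`, `audiometry_overall`, `screen_positive`,
#'   `rescreen_interval_months`, `refer_to_gp`.
#' @examples
#' co <- simulate_cohort(n = 20, seed = 3)
#' head(screen_cohort(co))
#' @export
screen_cohort <- function(subjects, threshold = 4L, assume_absent = FALSE) {
  factors <- derive_risk_factors(subjects, assume_absent = assume_absent)
  score <- cumulative_score(factors)
  stratum <- stratify_risk(score, threshold = threshold)
  hhie <- categorize_hhie(score_hhie(subjects))
  tone_cols <- c("heard_2k_left", "heard_500_left",
                 "heard_2k_right", "heard_500_right")
  missing_t <- setdiff(tone_cols, names(subjects))
  if (length(missing_t)) {
    stop_arhl("missing tone-trial column(s): %s",
              paste(missing_t, collapse = ", "))
  }
  aud <- two_step_binaural(subjects$heard_2k_left, subjects$heard_500_left,
                           subjects$heard_2k_right, subjects$heard_500_right)
  concl <- conclude_screen(stratum, hhie$abnormal, aud$overall == "failed")
  data.frame(
    subject_id = subjects$subject_id,
    risk_score = score,
    risk_stratum = concl$risk_stratum,
    hhie_total = hhie$total,
    hhie_category = hhie$category,
    audiometry_overall = aud$overall,
    screen_positive = concl$screen_positive,
    rescreen_interval_months = concl$rescreen_interval_months,
    refer_to_gp = concl$refer_to_gp)
}

#' Validate screen conclusions against the PTA reference
#'
#' Cross-tabulates the screen-positive calls against the binary
#' hearing-loss reference (better-ear average > 25 dB HL, computed from
#' the subjects' PTA threshold columns) and assembles the full metrics
#' bundle: predictive metrics, Cohen's kappa, the ROC of the cumulative
#' risk score, and the Spearman correlations of the better-ear average
#' with each screening component.
#'
#' @param subjects subjects table including the [pta_columns()].
#' @param conclusions matching conclusions from [screen_cohort()].
#' @return object of class `arhl_metrics`: list with `n`, counts `tp`,
#'   `fp`, `fn`, `tn`, the fraction and `*_pct` metrics of
#'   [matrix_metrics()], `kappa`, `auc`, `optimal_cutoff`, `youden_j`, and
#'   `spearman` (list `hhie`, `risk_score`, `audiometry`).
#' @export
validation_metrics <- function(subjects, conclusions) {
  if (nrow(subjects) != nrow(conclusions)) {
    stop_arhl("'subjects' and 'conclusions' must have matching rows")
  }
  pta <- pta_classify(subjects)
  truth <- pta$hearing_loss
  if (all(truth) || !any(truth)) {
    stop_arhl("reference standard has a single class; validation metrics undefined")
  }
  pred <- screen_positive_batch(conclusions)
  cm <- confusion(pred, truth)
  roc <- roc_curve(conclusions$risk_score, truth)
  bundle <- c(
    list(n = nrow(subjects), tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn),
    matrix_metrics(cm),
    list(kappa = cohen_kappa(cm),
         auc = roc$auc,
         optimal_cutoff = roc$optimal_cutoff,
         youden_j = roc$optimal_j,
         spearman = list(
           hhie = spearman_rho(pta$better_ear_avg, conclusions$hhie_total),
           risk_score = spearman_rho(pta$better_ear_avg,
                                     conclusions$risk_score),
           audiometry = spearman_rho(pta$better_ear_avg,
                                     as.numeric(conclusions$audiometry_overall == "failed")))))
  class(bundle) <- "arhl_metrics"
  bundle
}

#' @export
print.arhl_metrics <- function(x, ...) {
  cat(sprintf(
    "screen validation (n = %d): sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%, kappa %.3f, risk-score AUC %.3f (cutoff %g)\n",
    x$n, x$sensitivity_pct, x$specificity_pct, x$ppv_pct, x$npv_pct,
    x$kappa, x$auc, x$optimal_cutoff))
  invisible(x)
}
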