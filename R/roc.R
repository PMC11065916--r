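# ROC analysis of the cumulative risk score (or any numeric score where
# higher means more likely positive): midpoint cutoffs, Youden-optimal
# operating point, trapezoidal AUC.

#' ROC curve of a score against a binary reference
#'
#' Candidate cutoffs are the midpoints between consecutive distinct
#' observed scores plus two sentinels, one below the minimum and one above
#' the maximum. At each cutoff a subject is called positive when its score
#' exceeds the cutoff (for the integer risk score: score >= the next
#' integer above the cutoff). The AUC is the trapezoidal area over
#' (1 - specificity, sensitivity); the optimal cutoff maximises Youden's
#' J = sensitivity + specificity - 1, ties broken toward the smallest
#' cutoff (the most sensitive operating point) with a message.
#'
#' @param scores numeric vector (typically the integer cumulative risk
#'   score); higher values indicate higher risk.
#' @param labels logical vector of reference outcomes, same length; both
#'   classes must be present.
#' @return object of class `roc_curve`: list with `points` (data.frame of
#'   `cutoff`, `sensitivity`, `specificity`, `youden_j`, ordered by
#'   strictly increasing cutoff), `auc`, `optimal_cutoff`, `optimal_j`.
#' @examples
#' r <- roc_curve(scores = c(4, 5, 6, 1, 2, 3),
#'                labels = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' r$auc            # 1: perfect separation
#' r$optimal_cutoff # 3.5
#' @export
roc_curve <- function(scores, labels) {
  check_flag(labels, "labels")
  if (length(scores) != length(labels) || length(scores) == 0L) {
    stop_arhl("'scores' and 'labels' must have equal non-zero length")
  }
  if (anyNA(scores)) stop_arhl("missing scores not allowed")
  if (all(labels) || !any(labels)) {
    stop_arhl("both outcome classes must be present for ROC analysis")
  }
  s <- sort(unique(scores))
  cutoffs <- c(s[1L] - 0.5,
               if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2,
               s[length(s)] + 0.5)
  npos <- sum(labels)
  nneg <- sum(!labels)
  sens <- vapply(cutoffs, function(ct) sum(scores > ct & labels) / npos,
                 numeric(1))
  spec <- vapply(cutoffs, function(ct) sum(scores <= ct & !labels) / nneg,
                 numeric(1))
  j <- sens + spec - 1
  points <- data.frame(cutoff = cutoffs, sensitivity = sens,
                       specificity = spec, youden_j = j)
  # trapezoid over the ROC polyline; FPR decreases with increasing cutoff
  fpr <- 1 - spec
  auc <- sum((fpr[-length(fpr)] - fpr[-1L]) *
               (sens[-length(sens)] + sens[-1L]) / 2)
  best_j <- max(j)
  ties <- which(abs(j - best_j) < 1e-12)
  if (length(ties) > 1L) {
    message(sprintf(
      "Youden tie at J = %.3f across %d cutoffs; smallest (most sensitive) cutoff chosen",
      best_j, length(ties)))
  }
  structure(list(points = points, auc = auc,
                 optimal_cutoff = cutoffs[ties[1L]], optimal_j = best_j),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, optimal cutoff = %g (Youden J = %.3f), %d points\n",
              x$auc, x$optimal_cutoff, x$optimal_j, nrow(x$points)))
  invisible(x)
}

#' Convert a Youden midpoint cutoff to the operational integer threshold
#'
#' A midpoint cutoff k + 0.5 between integer scores classifies score
#' >= k + 1 as positive; the operational threshold is that smallest
#' positive-classified integer (e.g. midpoint 3.5 gives threshold 4).
#'
#' @param cutoff a half-integer midpoint.
#' @return the integer threshold, `ceiling(cutoff)`.
#' @examples
#' youden_threshold_to_operational(3.5)  # 4
#' @export
youden_threshold_to_operational <- function(cutoff) {
  if (length(cutoff) != 1L || is.na(cutoff) ||
      abs(cutoff - floor(cutoff) - 0.5) > 1e-9) {
    stop_arhl("'cutoff' must be a midpoint between consecutive integers (k + 0.5)")
  }
  as.integer(ceiling(cutoff))
}
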