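# Screening-test validation statistics: confusion matrix, predictive
# values, Cohen's kappa, Spearman rank correlation, and exhaustive
# reconstruction of integer 2x2 tables from rounded published metrics.

#' Build a confusion matrix from screen calls and the reference standard
#'
#' `truth = TRUE` means the reference condition (hearing loss) is present.
#'
#' @param pred logical vector of screen calls (positive = `TRUE`).
#' @param truth logical vector of reference outcomes, same length.
#' @return object of class `confusion_matrix`: a list with integer counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion(pred = c(FALSE, FALSE, TRUE), truth = c(TRUE, FALSE, TRUE))
#' @export
confusion <- function(pred, truth) {
  check_flag(pred, "pred")
  check_flag(truth, "truth")
  if (length(pred) != length(truth) || length(pred) == 0L) {
    stop_arhl("'pred' and 'truth' must have equal non-zero length")
  }
  confusion_matrix(tp = sum(pred & truth), fp = sum(pred & !truth),
                   fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn non-negative integer counts; total must be positive.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop_arhl("confusion-matrix counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop_arhl("confusion matrix must contain at least one observation")
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (n = %d)\n", x$tp + x$fp + x$fn + x$tn))
  print(matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
               dimnames = list(screen = c("positive", "negative"),
                               reference = c("loss", "no loss"))))
  invisible(x)
}

#' Predictive metrics of a confusion matrix
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp),
#' NPV tn/(tn+fn) and accuracy (tp+tn)/n, as fractions plus one-decimal
#' half-up-rounded percentages (`*_pct`), the precision at which such
#' metrics are conventionally published. A metric whose denominator is
#' zero is undefined and reported as `NA` (never `NaN`).
#'
#' @param m a `confusion_matrix`.
#' @return named list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` and the corresponding `*_pct` values.
#' @examples
#' matrix_metrics(confusion_matrix(tp = 51, fp = 20, fn = 0, tn = 38))
#' @export
matrix_metrics <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    sensitivity = safe_div(m$tp, m$tp + m$fn),
    specificity = safe_div(m$tn, m$tn + m$fp),
    ppv = safe_div(m$tp, m$tp + m$fp),
    npv = safe_div(m$tn, m$tn + m$fn),
    accuracy = (m$tp + m$tn) / (m$tp + m$fp + m$fn + m$tn))
  pct <- lapply(out, function(v) round_half_up(100 * v, 1))
  names(pct) <- paste0(names(out), "_pct")
  c(out, pct)
}

#' Cohen's kappa of a confusion matrix
#'
#' Chance-corrected agreement (po - pe)/(1 - pe) with
#' po = (tp + tn)/n and pe = \[(tp+fp)(tp+fn) + (fn+tn)(fp+tn)\]/n^2.
#' Degenerate marginals with pe = 1 leave kappa undefined (`NA`).
#'
#' @param m a `confusion_matrix`.
#' @return kappa in \[-1, 1\], or `NA` when undefined.
#' @examples
#' cohen_kappa(confusion_matrix(tp = 51, fp = 20, fn = 0, tn = 38))  # 0.640
#' @export
cohen_kappa <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  n <- m$tp + m$fp + m$fn + m$tn
  po <- (m$tp + m$tn) / n
  pe <- ((m$tp + m$fp) * (m$tp + m$fn) + (m$fn + m$tn) * (m$fp + m$tn)) / n^2
  if (1 - pe <= .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Spearman rank correlation with average ranks for ties
#'
#' Pearson correlation of the mid-ranks (ties receive the mean of the
#' ranks they occupy), computed directly from the rank vectors.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation in \[-1, 1\]; `NA` when either vector is constant.
#' @examples
#' spearman_rho(1:5, c(2, 4, 6, 8, 10))   # 1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_arhl("'x' and 'y' must have equal length >= 3")
  }
  if (anyNA(x) || anyNA(y)) stop_arhl("missing values not allowed")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(dx * dy) / sqrt(sx * sy)
}

#' Reconstruct integer confusion matrices from rounded published metrics
#'
#' Exhaustively enumerates every non-negative integer 2x2 matrix with the
#' given total and returns those whose sensitivity, specificity and PPV
#' round (half-up, one decimal) to the published percentages. Any of the
#' three percentages may be `NA` to leave that metric unconstrained. A
#' matrix with an undefined metric never matches a supplied constraint.
#'
#' @param n total number of subjects.
#' @param sensitivity_pct,specificity_pct,ppv_pct published one-decimal
#'   percentages in \[0, 100\], or `NA`.
#' @return data.frame of solutions with columns `tp`, `fp`, `fn`, `tn`
#'   (zero rows when the constraints are contradictory); attribute
#'   `unique` is `TRUE` when exactly one solution exists.
#' @examples
#' reconstruct_matrix(109, 100.0, 65.5, 71.8)  # unique: 51/20/0/38
#' @export
reconstruct_matrix <- function(n, sensitivity_pct = NA_real_,
                               specificity_pct = NA_real_,
                               ppv_pct = NA_real_) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n)) {
    stop_arhl("'n' must be a single positive integer")
  }
  for (p in c(sensitivity_pct, specificity_pct, ppv_pct)) {
    if (!is.na(p) && (p < 0 || p > 100)) {
      stop_arhl("percentages must lie in [0, 100]")
    }
  }
  g <- expand.grid(tp = 0:n, fp = 0:n, fn = 0:n)
  g <- g[g$tp + g$fp + g$fn <= n, ]
  g$tn <- n - g$tp - g$fp - g$fn
  match_pct <- function(num, den, target) {
    if (is.na(target)) return(rep(TRUE, length(num)))
    ok <- den > 0
    ok[ok] <- round_half_up(100 * num[ok] / den[ok], 1) == target
    ok
  }
  keep <- match_pct(g$tp, g$tp + g$fn, sensitivity_pct) &
    match_pct(g$tn, g$tn + g$fp, specificity_pct) &
    match_pct(g$tp, g$tp + g$fp, ppv_pct)
  out <- g[keep, c("tp", "fp", "fn", "tn"), drop = FALSE]
  out[] <- lapply(out, as.integer)
  rownames(out) <- NULL
  attr(out, "unique") <- nrow(out) == 1L
  out
}
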