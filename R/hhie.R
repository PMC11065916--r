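# HHIE-s (Hearing Handicap Inventory for the Elderly, screening version):
# 10 items, responses yes / sometimes / never scored 4 / 2 / 0; total 0-40.
# Items 1-5 are conventionally the emotional subscale, 6-10 situational;
# the subscales are carried for reporting but no decision uses them.

.hhie_levels <- c("yes", "sometimes", "never")
.hhie_points <- c(yes = 4L, sometimes = 2L, never = 0L)

#' CSV column names of the 10 HHIE-s item responses
#' @return character vector `hhie_q1` .. `hhie_q10`.
#' @export
hhie_columns <- function() paste0("hhie_q", 1:10)

.as_hhie_matrix <- function(responses) {
  if (is.data.frame(responses)) {
    missing_c <- setdiff(hhie_columns(), names(responses))
    if (length(missing_c)) {
      stop_arhl("missing HHIE-s column(s): %s", paste(missing_c, collapse = ", "))
    }
    responses <- as.matrix(responses[hhie_columns()])
  } else if (is.atomic(responses) && is.null(dim(responses))) {
    if (length(responses) != 10L) {
      stop_arhl("an HHIE-s response set must have exactly 10 items, got %d",
                length(responses))
    }
    responses <- matrix(responses, nrow = 1L)
  }
  if (!is.matrix(responses) || ncol(responses) != 10L) {
    stop_arhl("HHIE-s responses must be 10 items per subject")
  }
  responses[] <- tolower(trimws(responses))
  bad <- matrix(!(responses %in% .hhie_levels), nrow = nrow(responses))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_arhl("invalid HHIE-s response '%s' (subject row %d, item %d); must be yes/sometimes/never",
              responses[bad][1L], idx[1L], idx[2L])
  }
  responses
}

#' Score the HHIE-s questionnaire
#'
#' Total = 4 x (number of "yes") + 2 x (number of "sometimes"); always an
#' even value in 0..40. Response matching is case-insensitive.
#'
#' @param responses one response set (character vector of length 10) or a
#'   data.frame/matrix with one row per subject and the columns of
#'   [hhie_columns()].
#' @return integer vector of totals, one per subject.
#' @examples
#' score_hhie(rep("never", 10))                      # 0
#' score_hhie(c(rep("yes", 3), rep("sometimes", 2),
#'              rep("never", 5)))                    # 16
#' @export
score_hhie <- function(responses) {
  m <- .as_hhie_matrix(responses)
  as.integer(4L * rowSums(m == "yes") + 2L * rowSums(m == "sometimes"))
}

#' Categorise an HHIE-s total
#'
#' Totals 0-8 indicate no obvious impairment, 10-22 mild-to-moderate and
#' 24-40 severe; the abnormality flag is total >= 10. Odd totals are
#' unreachable under the 4/2/0 weights, so they are rejected as corrupted
#' input rather than rounded.
#'
#' @param total integer vector of HHIE-s totals (even, 0..40).
#' @return data.frame with columns `total`, `category` (factor:
#'   `no_obvious`, `mild_moderate`, `severe`) and `abnormal` (logical).
#' @examples
#' categorize_hhie(c(0, 8, 10, 24, 40))
#' @export
categorize_hhie <- function(total) {
  if (anyNA(total) || any(total < 0) || any(total > 40) ||
      any(total %% 2 != 0)) {
    stop_arhl("HHIE-s totals must be even values in 0..40 (got %s)",
              paste(utils::head(total[is.na(total) | total < 0 | total > 40 |
                                        total %% 2 != 0], 1L), collapse = ""))
  }
  category <- cut(total, breaks = c(-1, 8, 22, 40),
                  labels = c("no_obvious", "mild_moderate", "severe"))
  data.frame(total = as.integer(total), category = category,
             abnormal = total >= 10)
}
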