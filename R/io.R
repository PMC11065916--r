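# File I/O: subjects.csv / truth.csv / conclusions.csv / metrics.json.
# Booleans are serialised 0/1; decimals use '.'; the 0.5 kHz tone-trial
# count is blank when the tone was not administered. Output files are
# written via a temporary file and renamed, so a failure never leaves a
# partial file behind.

.bool_csv_fields <- c(
  "lives_alone", "noise_history", "family_deafness", "exercise_habit",
  "smoking", "drinking", "headset_habit", "hypertension", "diabetes",
  "hyperlipidemia", "cardio_cerebrovascular", "hyperuricemia",
  "hypothyroidism", "ototoxic_drug_history")

.tone_columns <- c("heard_2k_left", "heard_500_left",
                   "heard_2k_right", "heard_500_right")

.write_atomically <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(unlink(tmp))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

.write_csv <- function(df, path) {
  .write_atomically(function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE, na = "", quote = FALSE,
                     fileEncoding = "UTF-8")
  }, path)
}

#' Write a cohort to subjects.csv (and optionally truth.csv)
#'
#' @param cohort subjects table, e.g. from [simulate_cohort()].
#' @param subjects_path output CSV path for the screening inputs.
#' @param truth_path optional output CSV path for the latent truth columns
#'   (`subject_id`, `hearing_loss`, `better_ear_avg`, `grade`); only
#'   written when the cohort carries them.
#' @return invisibly, `subjects_path`.
#' @export
write_cohort <- function(cohort, subjects_path, truth_path = NULL) {
  cols <- c(profile_columns(), hhie_columns(), .tone_columns, pta_columns())
  cols <- intersect(cols, names(cohort))
  df <- as.data.frame(cohort)[cols]
  for (f in intersect(.bool_csv_fields, names(df))) {
    df[[f]] <- as.integer(df[[f]])
  }
  .write_csv(df, subjects_path)
  if (!is.null(truth_path)) {
    truth_cols <- c("true_hearing_loss", "true_better_ear_avg", "true_grade")
    if (!all(truth_cols %in% names(cohort))) {
      stop_arhl("cohort carries no truth columns; cannot write %s", truth_path)
    }
    truth <- data.frame(subject_id = cohort$subject_id,
                        hearing_loss = as.integer(cohort$true_hearing_loss),
                        better_ear_avg = cohort$true_better_ear_avg,
                        grade = as.character(cohort$true_grade))
    .write_csv(truth, truth_path)
  }
  invisible(subjects_path)
}

#' Read and validate a subjects.csv
#'
#' Checks the documented schema: required profile columns, unique subject
#' ids, 0/1 booleans, valid HHIE-s responses and tone-trial counts.
#' Unknown columns are kept but reported with a warning. Validation
#' errors name the offending row and column.
#'
#' @param path CSV path (UTF-8, comma-separated, header row).
#' @param assume_absent treat missing profile booleans as 0 (with a
#'   warning) instead of failing.
#' @return validated data.frame, one row per subject, booleans as logical.
#' @export
read_subjects <- function(path, assume_absent = FALSE) {
  if (!file.exists(path)) stop_arhl("input file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop_arhl("input file %s contains no subjects", path)
  known <- c(profile_columns(), hhie_columns(), .tone_columns, pta_columns())
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop_arhl("duplicate subject_id '%s'",
              df$subject_id[anyDuplicated(df$subject_id)])
  }
  for (f in intersect(.bool_csv_fields, names(df))) {
    v <- df[[f]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      bad <- which(!(is.na(v) | v %in% c(0, 1)))[1L]
      stop_arhl("row %d, column '%s': expected 0/1, got '%s'", bad, f, v[bad])
    }
    df[[f]] <- as.logical(v)
  }
  for (f in intersect(.tone_columns, names(df))) {
    v <- suppressWarnings(as.integer(df[[f]]))
    orig <- df[[f]]
    if (any(!is.na(orig) & orig != "" & is.na(v))) {
      stop_arhl("row %d, column '%s': expected a count 0..2",
                which(!is.na(orig) & orig != "" & is.na(v))[1L], f)
    }
    df[[f]] <- v
  }
  validate_profiles(df, assume_absent = assume_absent)
}

#' Write per-subject screening conclusions to CSV
#'
#' @param conclusions data.frame from [screen_cohort()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_conclusions <- function(conclusions, path) {
  df <- conclusions
  df$screen_positive <- as.integer(df$screen_positive)
  df$refer_to_gp <- as.integer(df$refer_to_gp)
  .write_csv(df, path)
}

#' Write a metrics bundle to JSON
#'
#' Full-precision fractions plus display strings at the conventional
#' one-decimal percent precision.
#'
#' @param metrics an `arhl_metrics` bundle from [validation_metrics()].
#' @param path output path for `metrics.json`.
#' @return invisibly, `path`.
#' @export
write_metrics_json <- function(metrics, path) {
  x <- unclass(metrics)
  x$display <- list(
    sensitivity = sprintf("%.1f%%", x$sensitivity_pct),
    specificity = sprintf("%.1f%%", x$specificity_pct),
    ppv = sprintf("%.1f%%", x$ppv_pct),
    npv = sprintf("%.1f%%", x$npv_pct),
    accuracy = sprintf("%.1f%%", x$accuracy_pct),
    kappa = sprintf("%.1f", round_half_up(x$kappa, 1)))
  .write_atomically(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }, path)
}

#' Run the screening pipeline on a subjects file
#'
#' Reads and validates `input`, screens every subject, writes the
#' conclusions CSV, and — when `metrics_out` is given — validates the
#' screen against the PTA reference columns of the same file and writes
#' the metrics bundle as JSON. No output file is left behind on failure.
#'
#' @param input path to subjects.csv.
#' @param output path for conclusions.csv.
#' @param metrics_out optional path for metrics.json; requires the
#'   [pta_columns()] in the input.
#' @param threshold operational risk-score threshold (default 4).
#' @param assume_absent treat missing profile booleans as absent.
#' @return invisibly, the conclusions data.frame.
#' @export
run_screen <- function(input, output, metrics_out = NULL, threshold = 4L,
                       assume_absent = FALSE) {
  subjects <- read_subjects(input, assume_absent = assume_absent)
  conclusions <- screen_cohort(subjects, threshold = threshold,
                               assume_absent = assume_absent)
  metrics <- NULL
  if (!is.null(metrics_out)) {
    if (!all(pta_columns() %in% names(subjects))) {
      stop_arhl("validation requested but PTA reference columns are missing from %s",
                input)
    }
    metrics <- validation_metrics(subjects, conclusions)
  }
  write_conclusions(conclusions, output)
  if (!is.null(metrics)) write_metrics_json(metrics, metrics_out)
  invisible(conclusions)
}
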