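# Risk-factor derivation, cumulative score and low/high stratification.
#
# A subject profile is one row of a data.frame with the columns listed in
# `profile_columns()`. Booleans are logical (0/1 on disk). The 18 indicator
# definitions are operational questionnaire definitions: the profile already
# carries resolved yes/no answers (e.g. smoking = "> 1 piece/day for 6
# months"), so this module applies no duration arithmetic of its own.

#' Canonical names and order of the 18 binary risk factors
#'
#' The fixed order determines CSV column order and the indicator order of
#' every [derive_risk_factors()] result.
#'
#' @return character vector of length 18.
#' @export
risk_factor_names <- function() {
  c("male", "overweight_obesity", "living_alone", "widowed_divorced",
    "noise_history", "family_deafness", "non_light_diet", "no_exercise",
    "smoking", "drinking", "headset_habit", "hypertension", "diabetes",
    "hyperlipidemia", "cardio_cerebrovascular", "hyperuricemia",
    "hypothyroidism", "ototoxic_drugs")
}

# profile boolean fields copied verbatim into the indicator vector
.copied_factor_fields <- c(
  living_alone = "lives_alone",
  noise_history = "noise_history",
  family_deafness = "family_deafness",
  smoking = "smoking",
  drinking = "drinking",
  headset_habit = "headset_habit",
  hypertension = "hypertension",
  diabetes = "diabetes",
  hyperlipidemia = "hyperlipidemia",
  cardio_cerebrovascular = "cardio_cerebrovascular",
  hyperuricemia = "hyperuricemia",
  hypothyroidism = "hypothyroidism",
  ototoxic_drugs = "ototoxic_drug_history")

#' Column names of a subject profile table
#'
#' @return character vector naming the demographic, lifestyle and
#'   chronic-disease columns expected in `subjects.csv`.
#' @export
profile_columns <- function() {
  c("subject_id", "age", "sex", "height", "weight", "bmi",
    "lives_alone", "marital_status", "noise_history", "family_deafness",
    "diet", "exercise_habit", "smoking", "drinking", "headset_habit",
    "hypertension", "diabetes", "hyperlipidemia", "cardio_cerebrovascular",
    "hyperuricemia", "hypothyroidism", "ototoxic_drug_history")
}

.profile_bool_fields <- c(
  "lives_alone", "noise_history", "family_deafness", "exercise_habit",
  "smoking", "drinking", "headset_habit", "hypertension", "diabetes",
  "hyperlipidemia", "cardio_cerebrovascular", "hyperuricemia",
  "hypothyroidism", "ototoxic_drug_history")

validate_profiles <- function(profiles, assume_absent = FALSE) {
  if (!is.data.frame(profiles) || nrow(profiles) < 1L) {
    stop_arhl("profiles must be a data.frame with at least one row")
  }
  needed <- setdiff(profile_columns(), c("height", "weight", "bmi"))
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols)) {
    stop_arhl("missing required profile column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  if (anyNA(profiles$age) || any(profiles$age < 60)) {
    stop_arhl("'age' must be present and >= 60 for every subject")
  }
  if (!all(profiles$sex %in% c("male", "female"))) {
    stop_arhl("'sex' must be 'male' or 'female'")
  }
  if (!all(profiles$marital_status %in% c("married", "widowed", "divorced"))) {
    bad <- which(!profiles$marital_status %in%
                   c("married", "widowed", "divorced"))[1L]
    stop_arhl("row %d: invalid marital_status '%s'", bad,
              profiles$marital_status[bad])
  }
  if (!all(profiles$diet %in% c("light", "non_light"))) {
    stop_arhl("'diet' must be 'light' or 'non_light'")
  }
  for (f in .profile_bool_fields) {
    v <- profiles[[f]]
    if (is.numeric(v)) v <- as.logical(v)
    if (anyNA(v)) {
      if (assume_absent) {
        warning(sprintf("missing '%s' treated as FALSE (assume_absent)", f),
                call. = FALSE)
        v[is.na(v)] <- FALSE
      } else {
        stop_arhl("missing value in required field '%s' (row %d)",
                  f, which(is.na(v))[1L])
      }
    }
    profiles[[f]] <- v
  }
  # BMI: present, or derivable from positive height (cm) and weight (kg)
  bmi <- if ("bmi" %in% names(profiles)) profiles$bmi else
    rep(NA_real_, nrow(profiles))
  need <- is.na(bmi)
  if (any(need)) {
    h <- if ("height" %in% names(profiles)) profiles$height else
      rep(NA_real_, nrow(profiles))
    w <- if ("weight" %in% names(profiles)) profiles$weight else
      rep(NA_real_, nrow(profiles))
    if (anyNA(h[need]) || anyNA(w[need])) {
      stop_arhl("field 'bmi' missing and not derivable (height/weight absent, row %d)",
                which(need & (is.na(h) | is.na(w)))[1L])
    }
    if (any(h[need] <= 0) || any(w[need] <= 0)) {
      stop_arhl("non-positive height or weight (row %d)",
                which(need & (h <= 0 | w <= 0))[1L])
    }
    bmi[need] <- w[need] / (h[need] / 100)^2
  }
  profiles$bmi <- bmi
  profiles
}

#' Derive the 18 binary risk-factor indicators from subject profiles
#'
#' Applies the operational definitions: `male` (sex), `overweight_obesity`
#' (BMI >= 24.0 kg/m^2, boundary inclusive; BMI derived as
#' weight / (height/100)^2 when absent), `widowed_divorced` (marital
#' status widowed or divorced), `non_light_diet` (diet not light),
#' `no_exercise` (no exercise habit); the remaining indicators are copied
#' from the corresponding yes/no profile fields. Age is deliberately not
#' an indicator.
#'
#' @param profiles data.frame of subject profiles (see [profile_columns()]);
#'   one row per subject.
#' @param assume_absent if `TRUE`, missing boolean fields are treated as
#'   `FALSE` with a warning instead of an error. Off by default: silent
#'   imputation is never the conservative choice in screening.
#' @return data.frame of 18 logical columns in [risk_factor_names()] order,
#'   one row per subject.
#' @examples
#' p <- data.frame(subject_id = "s1", age = 70, sex = "male", bmi = 24.0,
#'   lives_alone = FALSE, marital_status = "married", noise_history = FALSE,
#'   family_deafness = FALSE, diet = "light", exercise_habit = TRUE,
#'   smoking = FALSE, drinking = FALSE, headset_habit = FALSE,
#'   hypertension = TRUE, diabetes = FALSE, hyperlipidemia = FALSE,
#'   cardio_cerebrovascular = FALSE, hyperuricemia = FALSE,
#'   hypothyroidism = FALSE, ototoxic_drug_history = FALSE)
#' derive_risk_factors(p)
#' @export
derive_risk_factors <- function(profiles, assume_absent = FALSE) {
  profiles <- validate_profiles(profiles, assume_absent = assume_absent)
  out <- data.frame(
    male = profiles$sex == "male",
    overweight_obesity = profiles$bmi >= 24.0,
    living_alone = profiles$lives_alone,
    widowed_divorced = profiles$marital_status %in% c("widowed", "divorced"),
    noise_history = profiles$noise_history,
    family_deafness = profiles$family_deafness,
    non_light_diet = profiles$diet == "non_light",
    no_exercise = !profiles$exercise_habit,
    smoking = profiles$smoking,
    drinking = profiles$drinking,
    headset_habit = profiles$headset_habit,
    hypertension = profiles$hypertension,
    diabetes = profiles$diabetes,
    hyperlipidemia = profiles$hyperlipidemia,
    cardio_cerebrovascular = profiles$cardio_cerebrovascular,
    hyperuricemia = profiles$hyperuricemia,
    hypothyroidism = profiles$hypothyroidism,
    ototoxic_drugs = profiles$ototoxic_drug_history)
  stopifnot(identical(names(out), risk_factor_names()))
  out
}

#' Cumulative risk score: count of positive indicators
#'
#' @param factors data.frame (or named logical vector) holding the 18
#'   indicators of [risk_factor_names()].
#' @return integer vector of counts in 0..18, one per subject.
#' @export
cumulative_score <- function(factors) {
  if (is.logical(factors) && !is.null(names(factors))) {
    factors <- as.data.frame(as.list(factors))
  }
  missing_f <- setdiff(risk_factor_names(), names(factors))
  if (length(missing_f)) {
    stop_arhl("indicator(s) not set: %s", paste(missing_f, collapse = ", "))
  }
  m <- as.matrix(factors[risk_factor_names()])
  if (!is.logical(m) || anyNA(m)) {
    stop_arhl("all 18 indicators must be TRUE/FALSE with no missing values")
  }
  as.integer(rowSums(m))
}

#' Stratify a cumulative risk score into low/high risk
#'
#' High risk means score >= threshold (default 4); low risk otherwise.
#'
#' @param score integer vector of cumulative scores, each in 0..18.
#' @param threshold positive integer operational threshold (default 4).
#' @return character vector, `"low"` or `"high"`.
#' @examples
#' stratify_risk(c(0, 3, 4, 18))
#' @export
stratify_risk <- function(score, threshold = 4L) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 1) {
    stop_arhl("'threshold' must be a single integer >= 1")
  }
  if (anyNA(score) || any(score < 0) || any(score > 18)) {
    stop_arhl("'score' must be in 0..18 with no missing values")
  }
  ifelse(score >= threshold, "high", "low")
}
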