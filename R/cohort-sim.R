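# Synthetic cohort generator.
#
# Generative model, per subject:
#   age ~ Normal(age_mean, age_sd) truncated at age_min, rounded to years;
#   each of the 18 risk factors ~ Bernoulli(prevalence), independently by
#     default (an optional Gaussian-copula correlation matrix is accepted);
#   P(hearing loss) = inverse-logit(intercept + beta_age * (age - age_mean)
#     + sum(beta_factor * factor)), intercept calibrated by bisection so
#     the population prevalence hits target_prevalence;
#   grade = normal without loss, else drawn from grade_mix_given_loss;
#   better-ear four-frequency average ~ Uniform within the grade's dB band
#     (normal 0-25, ..., profound 91-cap); worse ear = better ear plus an
#     exponential non-negative offset; per-frequency thresholds add a
#     zero-mean tilt rising with frequency (high-frequency-sloping loss),
#     re-centred so each ear's four-frequency mean is preserved exactly;
#   HHIE-s items ~ shared-severity ordinal-logistic in the better-ear
#     average; tone perceptions ~ Bernoulli(inverse-logit((level -
#     threshold)/tone_slope)) per presentation, per ear, with the 0.5 kHz
#     tone administered only after the 2 kHz tone is heard twice.
# Everything is driven by one seed: identical params give bit-identical
# cohorts.

.default_prevalences <- c(
  male = 0.454, overweight_obesity = 0.05, living_alone = 0.075,
  widowed_divorced = 0.105, noise_history = 0.05, family_deafness = 0.05,
  non_light_diet = 0.279, no_exercise = 0.481, smoking = 0.177,
  drinking = 0.102, headset_habit = 0.05, hypertension = 0.643,
  diabetes = 0.307, hyperlipidemia = 0.092, cardio_cerebrovascular = 0.244,
  hyperuricemia = 0.170, hypothyroidism = 0.05, ototoxic_drugs = 0.05)

.default_coefficients <- c(
  age = 0.104, male = -0.056, overweight_obesity = -0.081,
  living_alone = 0, widowed_divorced = 0.148, noise_history = 1.357,
  family_deafness = 0, non_light_diet = 0.894, no_exercise = -0.385,
  smoking = 0, drinking = 0.741, headset_habit = 0, hypertension = 0.609,
  diabetes = 1.461, hyperlipidemia = 0.246, cardio_cerebrovascular = 0.362,
  hyperuricemia = 1.155, hypothyroidism = 1.645, ototoxic_drugs = 0)

.default_grade_mix <- c(mild = 0.485, moderate = 0.234,
                        moderately_severe = 0.078, severe = 0.013,
                        profound = 0.007)

#' Parameters of the synthetic cohort generator
#'
#' Defaults encode the cohort structure the screening protocol was built
#' for: community-dwelling adults 60+ (age 71.0 +/- 6.1 years), risk-factor
#' prevalences as observed in that population (hypertension 64.3%,
#' diabetes 30.7%, no exercise habit 48.1%, ...; factors without a
#' published prevalence default to 5%), hearing-loss log-odds from the
#' multivariate model (age 0.104/yr, diabetes 1.461, hypothyroidism 1.645,
#' noise history 1.357, ...; unstable or unreported estimates default to
#' 0), a hearing-loss prevalence target of 79.8%, and a grade mix within
#' the loss class of 48.5/23.4/7.8/1.3/0.7 (renormalised).
#'
#' @param n number of subjects (>= 1).
#' @param seed integer seed fixing the entire generation stream.
#' @param age_mean,age_sd,age_min age distribution in years (truncated
#'   normal).
#' @param factor_prevalences named numeric vector overriding any subset of
#'   the default per-factor prevalences (fractions in \[0, 1\]).
#' @param coefficients named numeric vector overriding any subset of the
#'   default log-odds (name `age` plus factor names).
#' @param intercept fixed logistic intercept; `NULL` (default) calibrates
#'   it to `target_prevalence` via [calibrate_intercept()].
#' @param target_prevalence population hearing-loss prevalence the
#'   calibrated intercept must reproduce.
#' @param grade_mix_given_loss named fractions for
#'   mild/moderate/moderately_severe/severe/profound, renormalised to 1.
#' @param hhie_mid better-ear average (dB HL) at which an HHIE-s item is
#'   50% likely to be at least "sometimes".
#' @param hhie_yes_gap additional dB between the "sometimes" and "yes"
#'   item thresholds.
#' @param hhie_slope dB scale of the per-item ordinal link. The default
#'   triple (42, 12, 5) makes a 40 dB better-ear average about 50% likely
#'   to score an abnormal HHIE-s total (>= 10).
#' @param tone_slope dB scale of the tone psychometric function; 0 or less
#'   means noiseless (a tone at or above threshold is always heard).
#' @param tilt_step dB spacing of the frequency tilt applied around each
#'   ear's average.
#' @param worse_ear_offset_mean mean (dB) of the exponential non-negative
#'   worse-ear offset.
#' @param profound_cap upper bound (dB HL) for simulated better-ear
#'   averages in the profound band.
#' @param calib_n quasi-population size used by intercept calibration.
#' @param factor_correlation optional 18 x 18 correlation matrix (factor
#'   order of [risk_factor_names()]) inducing factor dependence through a
#'   Gaussian copula; `NULL` (default) generates factors independently.
#' @return object of class `cohort_params` (a validated list).
#' @export
cohort_params <- function(n = 401L, seed = 1L,
                          age_mean = 71.0, age_sd = 6.1, age_min = 60,
                          factor_prevalences = NULL, coefficients = NULL,
                          intercept = NULL, target_prevalence = 0.798,
                          grade_mix_given_loss = NULL,
                          hhie_mid = 42, hhie_yes_gap = 12, hhie_slope = 5,
                          tone_slope = 3, tilt_step = 4.5,
                          worse_ear_offset_mean = 8, profound_cap = 110,
                          calib_n = 5e5, factor_correlation = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1) stop_arhl("'n' must be >= 1")
  if (length(seed) != 1L || is.na(seed)) stop_arhl("'seed' must be a single integer")
  prev <- .default_prevalences
  if (!is.null(factor_prevalences)) {
    bad <- setdiff(names(factor_prevalences), names(prev))
    if (length(bad)) stop_arhl("unknown factor(s): %s", paste(bad, collapse = ", "))
    prev[names(factor_prevalences)] <- factor_prevalences
  }
  if (any(prev < 0 | prev > 1)) stop_arhl("prevalences must lie in [0, 1]")
  beta <- .default_coefficients
  if (!is.null(coefficients)) {
    bad <- setdiff(names(coefficients), names(beta))
    if (length(bad)) stop_arhl("unknown coefficient(s): %s", paste(bad, collapse = ", "))
    beta[names(coefficients)] <- coefficients
  }
  if (any(!is.finite(beta))) stop_arhl("coefficients must be finite")
  mix <- .default_grade_mix
  if (!is.null(grade_mix_given_loss)) {
    bad <- setdiff(names(grade_mix_given_loss), names(mix))
    if (length(bad)) stop_arhl("unknown grade(s): %s", paste(bad, collapse = ", "))
    mix[names(grade_mix_given_loss)] <- grade_mix_given_loss
  }
  if (any(mix < 0) || sum(mix) <= 0) stop_arhl("grade mix must be non-negative and not all zero")
  mix <- mix / sum(mix)
  if (!is.null(intercept) && !is.finite(intercept)) stop_arhl("'intercept' must be finite")
  if (is.null(intercept) &&
      (target_prevalence <= 0 || target_prevalence >= 1)) {
    stop_arhl("'target_prevalence' must lie strictly inside (0, 1)")
  }
  if (!is.null(factor_correlation)) {
    if (!is.matrix(factor_correlation) ||
        !all(dim(factor_correlation) == 18L)) {
      stop_arhl("'factor_correlation' must be an 18 x 18 matrix")
    }
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, age_min = age_min,
    factor_prevalences = prev, coefficients = beta, intercept = intercept,
    target_prevalence = target_prevalence, grade_mix_given_loss = mix,
    hhie_mid = hhie_mid, hhie_yes_gap = hhie_yes_gap,
    hhie_slope = hhie_slope, tone_slope = tone_slope,
    tilt_step = tilt_step, worse_ear_offset_mean = worse_ear_offset_mean,
    profound_cap = profound_cap, calib_n = calib_n,
    factor_correlation = factor_correlation), class = "cohort_params")
}

#' Load cohort parameters from a YAML or JSON file
#'
#' The file holds any subset of the arguments of [cohort_params()];
#' `factor_prevalences`, `coefficients` and `grade_mix_given_loss` as
#' named maps. A full default file ships at
#' `system.file("extdata", "cohort-params.yaml", package = "arhlscreen")`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @param ... overrides applied on top of the file contents.
#' @return object of class `cohort_params`.
#' @export
cohort_params_from_file <- function(path, ...) {
  if (!file.exists(path)) stop_arhl("parameter file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads a bare key `n` as the boolean FALSE; undo that
  names(raw)[names(raw) == "FALSE"] <- "n"
  for (f in c("factor_prevalences", "coefficients", "grade_mix_given_loss")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  over <- list(...)
  raw[names(over)] <- over
  do.call(cohort_params, raw)
}

# draw the age / factor-indicator layer shared by calibration and
# simulation; assumes the RNG state has been set by the caller
.draw_covariates <- function(n, params) {
  age <- rnorm(n, params$age_mean, params$age_sd)
  while (any(bad <- age < params$age_min)) {
    age[bad] <- rnorm(sum(bad), params$age_mean, params$age_sd)
  }
  age <- round(age)
  prev <- params$factor_prevalences
  if (is.null(params$factor_correlation)) {
    factors <- matrix(runif(n * 18L) < rep(prev, each = n), nrow = n,
                      dimnames = list(NULL, risk_factor_names()))
  } else {
    z <- matrix(rnorm(n * 18L), nrow = n) %*% chol(params$factor_correlation)
    factors <- sweep(z, 2L, stats::qnorm(prev), "<")
    colnames(factors) <- risk_factor_names()
  }
  list(age = age, factors = factors)
}

.linear_predictor <- function(age, factors, params) {
  beta <- params$coefficients
  drop(beta["age"] * (age - params$age_mean) +
         factors %*% beta[risk_factor_names()])
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Finds, by bisection (`uniroot`), the intercept at which the population
#' mean of inverse-logit(intercept + linear predictor) equals
#' `target_prevalence`, the linear predictor being evaluated over a seeded
#' quasi-population of `calib_n` draws from the configured age and factor
#' distributions. The calibration stream is derived from the params seed
#' and leaves the caller's RNG state untouched.
#'
#' @param params a [cohort_params()] object.
#' @return the calibrated intercept (log-odds scale), accurate to within
#'   1e-4 on the prevalence scale over the quasi-population.
#' @examples
#' # with all coefficients zero the closed form is logit(target)
#' p <- cohort_params(n = 10, seed = 1, target_prevalence = 0.798,
#'   coefficients = c(age = 0, male = 0, overweight_obesity = 0,
#'     living_alone = 0, widowed_divorced = 0, noise_history = 0,
#'     family_deafness = 0, non_light_diet = 0, no_exercise = 0,
#'     smoking = 0, drinking = 0, headset_habit = 0, hypertension = 0,
#'     diabetes = 0, hyperlipidemia = 0, cardio_cerebrovascular = 0,
#'     hyperuricemia = 0, hypothyroidism = 0, ototoxic_drugs = 0))
#' abs(calibrate_intercept(p) - qlogis(0.798)) < 1e-6
#' @export
calibrate_intercept <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  target <- params$target_prevalence
  if (is.null(target) || target <= 0 || target >= 1) {
    stop_arhl("target prevalence %s is unattainable; must lie in (0, 1)",
              format(target))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed((params$seed + 777L) %% .Machine$integer.max)
  cov <- .draw_covariates(as.integer(params$calib_n), params)
  eta <- .linear_predictor(cov$age, cov$factors, params)
  f <- function(c0) mean(plogis(eta + c0)) - target
  uniroot(f, interval = c(-40, 40), tol = 1e-8)$root
}

#' Simulate a synthetic screening cohort
#'
#' Generates `params$n` subjects under the generative model described in
#' [cohort_params()]: full subject profiles, reference pure-tone
#' thresholds, HHIE-s item responses and two-step tone-trial outcomes,
#' plus the latent truth (hearing-loss indicator, better-ear average,
#' grade, linear predictor) retained for diagnostics. Every simulated
#' subject passes the input validation of all downstream modules.
#'
#' @param params a [cohort_params()] object (or `NULL` to use defaults
#'   with `n` and `seed` supplied directly).
#' @param n,seed convenience overrides when `params` is `NULL`.
#' @return data.frame of class `arhl_cohort`: the [profile_columns()],
#'   [hhie_columns()], tone-trial columns (`heard_2k_left`,
#'   `heard_500_left`, `heard_2k_right`, `heard_500_right`),
#'   [pta_columns()], and truth columns `true_hearing_loss`,
#'   `true_better_ear_avg`, `true_grade`, `true_linpred`. The calibrated
#'   intercept is attached as attribute `intercept`.
#' @examples
#' co <- simulate_cohort(n = 50, seed = 7)
#' mean(co$true_hearing_loss)
#' @export
simulate_cohort <- function(params = NULL, n = 401L, seed = 1L) {
  if (is.null(params)) params <- cohort_params(n = n, seed = seed)
  stopifnot(inherits(params, "cohort_params"))
  intercept <- params$intercept %||% calibrate_intercept(params)
  n <- params$n
  set.seed(params$seed)

  cov <- .draw_covariates(n, params)
  age <- cov$age
  factors <- cov$factors
  eta <- intercept + .linear_predictor(age, factors, params)
  loss <- runif(n) < plogis(eta)

  grades <- pta_grades()
  grade <- rep("normal", n)
  if (any(loss)) {
    grade[loss] <- sample(names(params$grade_mix_given_loss), sum(loss),
                          replace = TRUE, prob = params$grade_mix_given_loss)
  }
  band_lo <- c(normal = 0, mild = 25, moderate = 40, moderately_severe = 55,
               severe = 70, profound = 90)
  band_hi <- c(normal = 25, mild = 40, moderate = 55, moderately_severe = 70,
               severe = 90, profound = params$profound_cap)
  better_avg <- runif(n, band_lo[grade], band_hi[grade])
  worse_avg <- pmin(better_avg + rexp(n, 1 / params$worse_ear_offset_mean),
                    params$profound_cap)
  better_is_left <- runif(n) < 0.5

  # per-frequency thresholds: centred tilt rising with frequency
  ear_thresholds <- function(avg) {
    tilt <- outer(rep(1, n), c(-1.5, -0.5, 0.5, 1.5) * params$tilt_step) +
      matrix(runif(n * 4L, -1, 1), n)
    tilt <- tilt - rowMeans(tilt)
    avg + tilt
  }
  thr_better <- ear_thresholds(better_avg)
  thr_worse <- ear_thresholds(worse_avg)
  thr_left <- ifelse(matrix(better_is_left, n, 4), thr_better, thr_worse)
  thr_right <- ifelse(matrix(better_is_left, n, 4), thr_worse, thr_better)
  colnames(thr_left) <- paste0("pta_left_", c(500, 1000, 2000, 4000))
  colnames(thr_right) <- paste0("pta_right_", c(500, 1000, 2000, 4000))

  # HHIE-s: cumulative ordinal draw per item, shared severity in avg
  p_some <- plogis((better_avg - params$hhie_mid) / params$hhie_slope)
  p_yes <- plogis((better_avg - params$hhie_mid - params$hhie_yes_gap) /
                    params$hhie_slope)
  hhie <- matrix("never", n, 10L, dimnames = list(NULL, hhie_columns()))
  for (j in 1:10) {
    r <- runif(n)
    hhie[, j] <- ifelse(r < p_yes, "yes", ifelse(r < p_some, "sometimes",
                                                 "never"))
  }

  # tone trials per ear; the 0.5 kHz tone only after 2 kHz heard twice
  p_hear <- function(level, thr) {
    if (params$tone_slope <= 0) as.numeric(level >= thr)
    else plogis((level - thr) / params$tone_slope)
  }
  lv <- screen_tone_levels()
  ear_trial <- function(thr) {
    heard_2k <- rbinom(n, 2L, p_hear(lv[["tone_2k"]], thr[, 3L]))
    heard_500 <- rep(NA_integer_, n)
    adm <- heard_2k == 2L
    heard_500[adm] <- rbinom(sum(adm), 2L, p_hear(lv[["tone_500"]],
                                                  thr[adm, 1L]))
    list(h2k = heard_2k, h500 = heard_500)
  }
  left_trial <- ear_trial(thr_left)
  right_trial <- ear_trial(thr_right)

  # back-fill profile fields consistent with the drawn indicators
  sex <- ifelse(factors[, "male"], "male", "female")
  marital <- rep("married", n)
  wd <- factors[, "widowed_divorced"]
  if (any(wd)) {
    marital[wd] <- sample(c("widowed", "divorced"), sum(wd), replace = TRUE,
                          prob = c(36, 6))   # observed widowed:divorced mix
  }
  bmi <- ifelse(factors[, "overweight_obesity"], runif(n, 24, 32),
                runif(n, 18.5, 23.9))
  height <- round(rnorm(n, 162.1, 6), 1)
  weight <- round(bmi * (height / 100)^2, 1)
  bmi <- round(bmi, 2)

  out <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    age = as.integer(age), sex = sex, height = height, weight = weight,
    bmi = bmi,
    lives_alone = factors[, "living_alone"],
    marital_status = marital,
    noise_history = factors[, "noise_history"],
    family_deafness = factors[, "family_deafness"],
    diet = ifelse(factors[, "non_light_diet"], "non_light", "light"),
    exercise_habit = !factors[, "no_exercise"],
    smoking = factors[, "smoking"],
    drinking = factors[, "drinking"],
    headset_habit = factors[, "headset_habit"],
    hypertension = factors[, "hypertension"],
    diabetes = factors[, "diabetes"],
    hyperlipidemia = factors[, "hyperlipidemia"],
    cardio_cerebrovascular = factors[, "cardio_cerebrovascular"],
    hyperuricemia = factors[, "hyperuricemia"],
    hypothyroidism = factors[, "hypothyroidism"],
    ototoxic_drug_history = factors[, "ototoxic_drugs"])
  out <- cbind(out, as.data.frame(hhie),
               data.frame(heard_2k_left = left_trial$h2k,
                          heard_500_left = left_trial$h500,
                          heard_2k_right = right_trial$h2k,
                          heard_500_right = right_trial$h500),
               as.data.frame(thr_left),
               as.data.frame(thr_right),
               data.frame(true_hearing_loss = loss,
                          true_better_ear_avg = better_avg,
                          true_grade = factor(grade, levels = grades),
                          true_linpred = eta))
  attr(out, "intercept") <- intercept
  class(out) <- c("arhl_cohort", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Operating characteristics of the full protocol on a simulated cohort
#'
#' Runs the complete screen (risk factors, HHIE-s, two-step audiometry,
#' triage) on the cohort and validates the screen calls against the
#' pure-tone reference computed from the cohort's own threshold columns.
#'
#' @param cohort an `arhl_cohort` (or any subject table with the PTA
#'   reference columns present).
#' @param threshold operational risk-score threshold (default 4).
#' @return the metrics bundle of [validation_metrics()].
#' @export
protocol_operating_characteristics <- function(cohort, threshold = 4L) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop_arhl("'cohort' must be a non-empty data.frame")
  }
  conclusions <- screen_cohort(cohort, threshold = threshold)
  validation_metrics(cohort, conclusions)
}
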