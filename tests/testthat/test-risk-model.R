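# risk-factor derivation, cumulative score, stratification

test_that("an all-negative profile derives an all-false indicator vector", {
  f <- derive_risk_factors(make_profile())
  expect_identical(names(f), risk_factor_names())
  expect_length(names(f), 18L)
  expect_true(all(!as.logical(f[1, ])))
  expect_identical(cumulative_score(f), 0L)
})

test_that("indicator definitions follow the operational rules", {
  # BMI boundary is inclusive at 24.0
  expect_true(derive_risk_factors(make_profile(sex = "male", bmi = 24.0))$overweight_obesity)
  expect_false(derive_risk_factors(make_profile(bmi = 23.99))$overweight_obesity)
  # BMI derived from height/weight when absent: 64 / 1.60^2 = 25.0
  p <- make_profile(height = 160, weight = 64, bmi = NA_real_)
  expect_true(derive_risk_factors(p)$overweight_obesity)
  # marital status and diet recodes
  expect_true(derive_risk_factors(make_profile(marital_status = "widowed"))$widowed_divorced)
  expect_true(derive_risk_factors(make_profile(marital_status = "divorced"))$widowed_divorced)
  expect_true(derive_risk_factors(make_profile(diet = "non_light"))$non_light_diet)
  expect_true(derive_risk_factors(make_profile(exercise_habit = FALSE))$no_exercise)
  expect_true(derive_risk_factors(make_profile(sex = "male"))$male)
})

test_that("cumulative score counts set indicators (explicit-sum oracle)", {
  f <- derive_risk_factors(make_profile(sex = "male", hypertension = TRUE,
                                        diabetes = TRUE, smoking = TRUE))
  expect_identical(cumulative_score(f), 4L)
  # all 18 set
  all_pos <- make_profile(sex = "male", bmi = 30, lives_alone = TRUE,
    marital_status = "widowed", noise_history = TRUE, family_deafness = TRUE,
    diet = "non_light", exercise_habit = FALSE, smoking = TRUE,
    drinking = TRUE, headset_habit = TRUE, hypertension = TRUE,
    diabetes = TRUE, hyperlipidemia = TRUE, cardio_cerebrovascular = TRUE,
    hyperuricemia = TRUE, hypothyroidism = TRUE, ototoxic_drug_history = TRUE)
  expect_identical(cumulative_score(derive_risk_factors(all_pos)), 18L)
  # property: score equals an explicit sum over fields on random vectors
  set.seed(101)
  for (i in 1:25) {
    v <- as.data.frame(as.list(setNames(runif(18) < 0.5, risk_factor_names())))
    expect_identical(cumulative_score(v), as.integer(sum(unlist(v))))
  }
})

test_that("stratification splits at the threshold and is monotone", {
  expect_identical(stratify_risk(c(0L, 3L, 4L, 18L)),
                   c("low", "low", "high", "high"))
  expect_identical(stratify_risk(5L, threshold = 6L), "low")
  # setting one more indicator never lowers the stratum
  set.seed(7)
  for (i in 1:25) {
    v <- setNames(runif(18) < 0.4, risk_factor_names())
    off <- which(!v)
    if (!length(off)) next
    v2 <- v
    v2[sample(off, 1)] <- TRUE
    s1 <- cumulative_score(as.data.frame(as.list(v)))
    s2 <- cumulative_score(as.data.frame(as.list(v2)))
    expect_identical(s2, s1 + 1L)
    expect_false(stratify_risk(s1) == "high" && stratify_risk(s2) == "low")
  }
})

test_that("invalid profiles are rejected with named errors", {
  expect_error(derive_risk_factors(make_profile(age = 59L)), "age")
  expect_error(derive_risk_factors(make_profile(sex = "other")), "sex")
  expect_error(derive_risk_factors(make_profile(marital_status = "single")),
               "marital_status")
  expect_error(
    derive_risk_factors(make_profile(bmi = NA_real_, height = -160, weight = 64)),
    "height")
  expect_error(
    derive_risk_factors(make_profile(bmi = NA_real_, height = NA_real_)),
    "bmi")
  expect_error(derive_risk_factors(make_profile(diabetes = NA)), "diabetes")
  expect_error(stratify_risk(-1L), "score")
  expect_error(stratify_risk(3L, threshold = 0L), "threshold")
})

test_that("assume_absent imputes FALSE with a warning, never silently", {
  p <- make_profile(diabetes = NA)
  expect_warning(f <- derive_risk_factors(p, assume_absent = TRUE), "diabetes")
  expect_false(f$diabetes)
})
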