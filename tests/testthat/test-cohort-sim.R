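# synthetic cohort generator: calibration, determinism, structure

zero_betas <- function() {
  setNames(rep(0, 19), c("age", risk_factor_names()))
}

test_that("intercept calibration has the closed form when betas vanish", {
  p5 <- cohort_params(n = 10, seed = 1, coefficients = zero_betas(),
                      target_prevalence = 0.5, calib_n = 1e4)
  expect_equal(calibrate_intercept(p5), 0, tolerance = 1e-6)
  p8 <- cohort_params(n = 10, seed = 1, coefficients = zero_betas(),
                      target_prevalence = 0.798, calib_n = 1e4)
  expect_equal(calibrate_intercept(p8), qlogis(0.798), tolerance = 1e-6)
})

test_that("unattainable prevalence targets are rejected", {
  expect_error(cohort_params(target_prevalence = 1.0), "target_prevalence")
  expect_error(cohort_params(target_prevalence = 0), "target_prevalence")
})

test_that("calibration leaves the caller's RNG stream untouched", {
  p <- cohort_params(n = 10, seed = 3, calib_n = 1e4)
  set.seed(555)
  a <- runif(3)
  set.seed(555)
  invisible(calibrate_intercept(p))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("identical params and seed give bit-identical cohorts", {
  p <- cohort_params(n = 300, seed = 17, calib_n = 1e4)
  expect_identical(simulate_cohort(p), simulate_cohort(p))
  # a different seed changes the cohort
  p2 <- cohort_params(n = 300, seed = 18, calib_n = 1e4)
  expect_false(identical(simulate_cohort(p), simulate_cohort(p2)))
})

test_that("noiseless tones are heard exactly when at or above threshold", {
  p <- cohort_params(n = 400, seed = 5, tone_slope = 0, calib_n = 1e4)
  co <- simulate_cohort(p)
  # an ear whose true thresholds make both tones audible must pass
  audible_left <- co$pta_left_2000 <= 42 & co$pta_left_500 <= 47
  res <- two_step_binaural(co$heard_2k_left, co$heard_500_left,
                           co$heard_2k_right, co$heard_500_right)
  expect_true(all(res$left[audible_left] == "passed"))
  # and an ear failing the 2 kHz level can never report the 0.5 kHz tone
  expect_true(all(is.na(co$heard_500_left[co$pta_left_2000 > 42])))
})

test_that("latent truth is consistent with the PTA reference columns", {
  co <- simulate_cohort(cohort_params(n = 1500, seed = 9, calib_n = 1e4))
  pta <- pta_classify(co)
  expect_equal(pta$better_ear_avg, co$true_better_ear_avg, tolerance = 1e-9)
  expect_identical(as.character(pta$grade), as.character(co$true_grade))
  expect_identical(pta$hearing_loss, co$true_hearing_loss)
  expect_identical(co$true_hearing_loss,
                   as.character(co$true_grade) != "normal")
})

test_that("severity is monotone across grades in a simulated cohort", {
  co <- simulate_cohort(cohort_params(n = 2000, seed = 21, calib_n = 1e4))
  hhie_total <- score_hhie(co)
  failed <- two_step_binaural(co$heard_2k_left, co$heard_500_left,
                              co$heard_2k_right,
                              co$heard_500_right)$overall == "failed"
  by_grade <- split(seq_len(nrow(co)), co$true_grade, drop = FALSE)
  by_grade <- by_grade[lengths(by_grade) > 0]
  mean_hhie <- vapply(by_grade, function(i) mean(hhie_total[i]), numeric(1))
  fail_rate <- vapply(by_grade, function(i) mean(failed[i]), numeric(1))
  expect_true(all(diff(mean_hhie) >= 0))
  expect_true(all(diff(fail_rate) >= 0))
})

test_that("every simulated subject passes downstream validation end to end", {
  co <- simulate_cohort(cohort_params(n = 250, seed = 13, calib_n = 1e4))
  expect_silent(concl <- screen_cohort(co))
  expect_identical(nrow(concl), 250L)
  m <- protocol_operating_characteristics(co)
  expect_gt(m$auc, 0.5)  # positive generative betas force discrimination
  expect_true(all(c("tp", "fp", "fn", "tn", "kappa", "spearman") %in%
                    names(m)))
})

test_that("empirical factor prevalences track their parameters", {
  co <- simulate_cohort(cohort_params(n = 20000, seed = 25, calib_n = 1e4))
  f <- derive_risk_factors(co)
  for (nm in c("hypertension", "diabetes", "no_exercise", "male")) {
    target <- cohort_params()$factor_prevalences[[nm]]
    se <- sqrt(target * (1 - target) / 20000)
    expect_lt(abs(mean(f[[nm]]) - target), 4 * se)
  }
})

test_that("a correlation hook induces factor dependence via the copula", {
  R <- diag(18)
  R[1, 2] <- R[2, 1] <- 0.8   # male ~ overweight, strongly linked
  p <- cohort_params(n = 4000, seed = 33, factor_correlation = R,
                     calib_n = 1e4)
  co <- simulate_cohort(p)
  f <- derive_risk_factors(co)
  expect_gt(stats::cor(f$male, f$overweight_obesity), 0.1)
})

test_that("parameter files round-trip through the loader", {
  path <- system.file("extdata", "cohort-params.yaml", package = "arhlscreen")
  p <- cohort_params_from_file(path, n = 50, seed = 2)
  expect_s3_class(p, "cohort_params")
  expect_identical(p$n, 50L)
  expect_equal(p$coefficients[["diabetes"]], 1.461)
  expect_equal(p$factor_prevalences[["hypertension"]], 0.643)
  expect_equal(sum(p$grade_mix_given_loss), 1)
})

test_that("invalid generator parameters fail before any draw", {
  expect_error(cohort_params(n = 0), "n")
  expect_error(cohort_params(factor_prevalences = c(bogus = 0.5)), "bogus")
  expect_error(cohort_params(factor_prevalences = c(male = 1.5)), "\\[0, 1\\]")
  expect_error(cohort_params(coefficients = c(diabetes = Inf)), "finite")
  expect_error(cohort_params(factor_correlation = diag(3)), "18 x 18")
})
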