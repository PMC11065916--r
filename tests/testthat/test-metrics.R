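# confusion-matrix metrics, kappa, Spearman, matrix reconstruction

test_that("confusion cross-tabulates calls against the reference", {
  m <- confusion(pred = c(TRUE, TRUE), truth = c(TRUE, FALSE))
  expect_identical(unlist(m[c("tp", "fp", "fn", "tn")]),
                   c(tp = 1L, fp = 1L, fn = 0L, tn = 0L))
  m <- confusion(pred = rep(TRUE, 5), truth = rep(TRUE, 5))
  expect_identical(m$tp, 5L)
  expect_identical(m$fp + m$fn + m$tn, 0L)
  m <- confusion(pred = c(FALSE, FALSE, TRUE), truth = c(TRUE, FALSE, TRUE))
  expect_identical(unlist(m[c("tp", "fp", "fn", "tn")]),
                   c(tp = 1L, fp = 0L, fn = 1L, tn = 1L))
  expect_error(confusion(TRUE, c(TRUE, FALSE)), "length")
})

test_that("predictive metrics reproduce the published verification table", {
  mm <- matrix_metrics(confusion_matrix(tp = 51, fp = 20, fn = 0, tn = 38))
  expect_equal(mm$sensitivity_pct, 100.0)
  expect_equal(mm$specificity_pct, 65.5)
  expect_equal(mm$ppv_pct, 71.8)
  expect_equal(mm$npv_pct, 100.0)
  mm2 <- matrix_metrics(confusion_matrix(1, 0, 0, 1))
  expect_true(all(unlist(mm2[c("sensitivity", "specificity", "ppv", "npv",
                               "accuracy")]) == 1))
})

test_that("NPV is forced to 100% whenever there are no false negatives", {
  set.seed(31)
  for (i in 1:20) {
    m <- confusion_matrix(sample(0:50, 1), sample(0:50, 1), 0,
                          sample(1:50, 1))
    expect_equal(matrix_metrics(m)$npv, 1)
  }
})

test_that("zero-denominator metrics are undefined (NA), not NaN", {
  mm <- matrix_metrics(confusion_matrix(0, 0, 0, 5))
  expect_true(is.na(mm$sensitivity) && !is.nan(mm$sensitivity))
  expect_true(is.na(mm$ppv))
  expect_equal(mm$specificity, 1)
})

test_that("kappa matches the chance-corrected agreement formula", {
  expect_equal(cohen_kappa(confusion_matrix(10, 0, 0, 5)), 1)
  expect_equal(cohen_kappa(confusion_matrix(51, 20, 0, 38)), 0.640,
               tolerance = 1e-3)
  expect_equal(round_half_up(cohen_kappa(confusion_matrix(51, 20, 0, 38))),
               0.6)
  # all-positive calls against mixed truth: agreement equals chance
  expect_equal(cohen_kappa(confusion(rep(TRUE, 4),
                                     c(TRUE, TRUE, FALSE, TRUE))), 0)
  # degenerate marginals (everyone positive on both) -> undefined
  expect_true(is.na(cohen_kappa(confusion_matrix(5, 0, 0, 0))))
})

test_that("kappa is bounded, symmetric under label swap, 1 iff no errors", {
  set.seed(99)
  for (i in 1:200) {
    m <- random_confusion()
    k <- cohen_kappa(m)
    if (is.na(k)) next
    expect_gte(k, -1)
    expect_lte(k, 1)
    swapped <- confusion_matrix(m$tn, m$fn, m$fp, m$tp)
    expect_equal(cohen_kappa(swapped), k)
    if (m$fp == 0 && m$fn == 0) expect_equal(k, 1)
    if (k == 1) expect_true(m$fp == 0 && m$fn == 0)
  }
})

test_that("Spearman uses average ranks and handles ties", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  x <- c(1, 2, 2, 3)
  y <- c(1, 3, 2, 4)
  # average-rank Pearson oracle: ranks (1, 2.5, 2.5, 4) vs (1, 3, 2, 4)
  oracle <- stats::cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4))
  expect_equal(spearman_rho(x, y), oracle)
  expect_equal(spearman_rho(x, y), stats::cor(x, y, method = "spearman"))
  expect_true(is.na(spearman_rho(c(1, 1, 1), 1:3)))
  expect_error(spearman_rho(1:3, 1:4), "length")
})

test_that("Spearman agrees with stats::cor on random tied data", {
  set.seed(17)
  for (i in 1:50) {
    x <- sample(1:6, 30, replace = TRUE)
    y <- x + sample(-2:2, 30, replace = TRUE)
    expect_equal(spearman_rho(x, y), stats::cor(x, y, method = "spearman"))
  }
})

test_that("matrix reconstruction from rounded metrics is exact and unique", {
  sol <- reconstruct_matrix(109, 100.0, 65.5, 71.8)
  expect_identical(nrow(sol), 1L)
  expect_true(attr(sol, "unique"))
  expect_identical(unlist(sol[1, ]), c(tp = 51L, fp = 20L, fn = 0L, tn = 38L))

  sol2 <- reconstruct_matrix(2, 100.0, 100.0, 100.0)
  expect_identical(unlist(sol2[1, ]), c(tp = 1L, fp = 0L, fn = 0L, tn = 1L))

  # contradictory constraints: sensitivity 0 but a PPV needing tp > 0
  expect_identical(nrow(reconstruct_matrix(10, 0.0, 100.0, 100.0)), 0L)
})

test_that("reconstructed matrices reproduce the input percentages", {
  targets <- list(c(80.0, 50.0, NA), c(66.7, 75.0, 66.7), c(100.0, 65.5, 71.8))
  for (tg in targets) {
    sol <- reconstruct_matrix(24, tg[1], tg[2], tg[3])
    for (i in seq_len(nrow(sol))) {
      mm <- matrix_metrics(confusion_matrix(sol$tp[i], sol$fp[i],
                                            sol$fn[i], sol$tn[i]))
      expect_equal(mm$sensitivity_pct, tg[1])
      expect_equal(mm$specificity_pct, tg[2])
      if (!is.na(tg[3])) expect_equal(mm$ppv_pct, tg[3])
    }
  }
})
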