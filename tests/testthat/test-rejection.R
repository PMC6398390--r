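test_that("pool-adjacent-violators matches hand computation and isoreg", {
  iso <- isotonic_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(iso$y, c(0.5, 0.5, 1))

  # tie-free random data: must agree with stats::isoreg exactly
  set.seed(4)
  for (trial in 1:5) {
    x <- sample(seq(0, 1, by = 0.001), 40)
    y <- stats::rnorm(40)
    ours <- isotonic_fit(x, y)
    ref <- stats::isoreg(x, y)
    expect_equal(ours$y, ref$yf, tolerance = 1e-10)  # yf is in sorted-x order
  }
})

test_that("isotonic fit is monotone and invariant to monotone score transforms", {
  set.seed(9)
  s <- stats::rnorm(60)
  lab <- as.numeric(stats::runif(60) < stats::plogis(2 * s))
  f1 <- isotonic_fit(s, lab)
  expect_true(all(diff(f1$y) >= -1e-12))
  f2 <- isotonic_fit(exp(s), lab)  # strictly increasing transform
  expect_equal(f1$y, f2$y, tolerance = 1e-12)
})

test_that("minimum-expected-cost decisions follow the posterior bands", {
  expect_equal(decide(0.9, 0.2), 1L)
  expect_equal(decide(0.5, 0.5), 0L)
  expect_equal(decide(0.1, 0.2), -1L)
  # boundaries reject
  expect_equal(decide(0.2, 0.2), 0L)
  expect_equal(decide(0.8, 0.2), 0L)
  expect_error(decide(1.2, 0.2), "eta")
  expect_error(decide(0.5, 0.7), "d must")

  # band nesting: anything rejected at larger d is rejected at smaller d
  etas <- seq(0, 1, by = 0.01)
  for (pair in list(c(0.1, 0.3), c(0.2, 0.45), c(0.3, 0.5))) {
    r_small <- decide(etas, pair[1]) == 0L
    r_large <- decide(etas, pair[2]) == 0L
    expect_true(all(r_small[r_large]))
  }
  # band shrinks to {1/2} as d -> 1/2
  expect_equal(sum(decide(etas, 0.5) == 0L), 1L)
})

test_that("rejection-rate operating mode rejects posteriors nearest 1/2", {
  r0 <- decide_at_rejection_rate(c(0.1, 0.45, 0.9), 0)
  expect_equal(r0$decisions, c(-1L, -1L, 1L))
  expect_equal(r0$achieved_rr, 0)

  r <- decide_at_rejection_rate(c(0.1, 0.45, 0.9), 0.34)
  expect_equal(r$decisions, c(-1L, 0L, 1L))

  tie <- decide_at_rejection_rate(rep(0.7, 5), 0.4)
  expect_equal(which(tie$decisions == 0L), c(1L, 2L))

  expect_error(decide_at_rejection_rate(c(0.2, 0.8), 1), "rejection rate")
})

test_that("classified subsets are nested along a rejection-rate grid", {
  set.seed(12)
  eta <- stats::runif(50)
  grid <- seq(0, 0.8, by = 0.1)
  prev <- rep(TRUE, 50)
  for (rr in grid) {
    cls <- decide_at_rejection_rate(eta, rr)$decisions != 0L
    expect_true(all(prev[!cls] | !cls[!cls]))  # vacuous guard
    expect_true(all(cls <= prev))              # classified set shrinks
    prev <- cls
  }
})

test_that("metrics on the classified subset count the confusion matrix", {
  m <- rejection_metrics(c(1L, 1L, -1L, -1L), c(1, 1, -1, -1),
                         eta = c(0.9, 0.8, 0.1, 0.2))
  expect_equal(m$ACC, 1); expect_equal(m$SN, 1); expect_equal(m$SP, 1)
  expect_equal(m$AUC, 1); expect_equal(m$RR, 0)

  m2 <- rejection_metrics(c(1L, 0L, -1L), c(1, 1, -1))
  expect_equal(m2$RR, 1 / 3)
  expect_equal(m2$ACC, 1)
  expect_equal(m2$TP + m2$FP + m2$TN + m2$FN, m2$n_classified)

  expect_error(rejection_metrics(c(0L, 0L), c(1, -1)), "rejected")
})

test_that("accuracy-rejection curve improves accuracy on calibrated scores", {
  set.seed(21)
  n <- 600
  eta_true <- stats::runif(n)
  y <- ifelse(stats::runif(n) < eta_true, 1, -1)
  curve <- accuracy_rejection_curve(eta_true, y, rr_grid = c(0, 0.3))
  expect_equal(curve$n_rejected[1], 0)
  expect_gt(curve$ACC[2], curve$ACC[1])
  # RR = 0 row equals plain thresholding at 1/2
  plain <- rejection_metrics(ifelse(eta_true > 0.5, 1L, -1L), y, eta_true)
  expect_equal(curve$ACC[1], plain$ACC)
})

test_that("out-of-fold calibration yields a monotone bounded map", {
  g <- separable_dataset(n = 90, p = 3, seed = 17, bins = 4)
  m <- fit_rules(g$data, fit_config(C = 2, d = 0.4, bins = 4,
                                    calibration_folds = 3))
  cm <- calibrate(m, g$data)
  expect_s3_class(cm, "calibrated_model")
  expect_true(all(diff(cm$calibration$y) >= -1e-12))
  eta <- predict(cm, g$data$X, type = "eta")
  expect_true(all(eta >= 1e-6 & eta <= 1 - 1e-6))
  # separable data: calibrated decisions track the labels closely
  dec <- predict(cm, g$data$X, type = "decision")
  agree <- mean(dec[dec != 0L] == g$data$y[dec != 0L])
  expect_gt(agree, 0.9)

  expect_error(calibrate(m, g$data, folds = 80), "stratification")
})
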