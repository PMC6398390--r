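test_that("model files round-trip to identical predictions", {
  g <- separable_dataset(n = 100, p = 4, seed = 23, bins = 5)
  m <- fit_rules(g$data, fit_config(C = 3, d = 0.4, bins = 5))
  cm <- calibrate(m, g$data, folds = 3)
  path <- tempfile(fileext = ".json")
  save_model(cm, path)
  cm2 <- load_model(path)

  set.seed(77)
  Xnew <- matrix(stats::runif(100 * 4), 100, 4)
  expect_identical(predict(cm, Xnew, type = "score"),
                   predict(cm2, Xnew, type = "score"))
  expect_identical(predict(cm, Xnew, type = "eta"),
                   predict(cm2, Xnew, type = "eta"))

  # plain rule model too
  p2 <- tempfile(fileext = ".json")
  save_model(m, p2)
  expect_identical(predict(m, Xnew), predict(load_model(p2), Xnew))
})

test_that("corrupt and unsupported model files error clearly", {
  g <- separable_dataset(n = 60, p = 2, seed = 29, bins = 3)
  m <- fit_rules(g$data, fit_config(C = 2, bins = 3))
  path <- tempfile(fileext = ".json")
  save_model(m, path)

  txt <- readLines(path)
  writeLines(txt[1:(length(txt) %/% 2)], path)
  expect_error(load_model(path), "parse")

  p3 <- tempfile(fileext = ".json")
  save_model(m, p3)
  txt <- readLines(p3)
  writeLines(sub('"format_version": "1"', '"format_version": "99"', txt), p3)
  expect_error(load_model(p3), "version")
})

test_that("explanations decompose the score exactly", {
  r1 <- conjunction_rule(1L, 0.5, Inf)
  r2 <- conjunction_rule(2L, -Inf, 0.3)
  m <- make_toy_model(list(r1, r2), c(0.7, -0.5), -0.1, p = 2)

  ex <- explain_subject(m, c(0.9, 0.9), top_k = 5)
  expect_equal(ex$score, 0.7 - 0.1)
  expect_false(ex$truncated)
  expect_equal(ex$displayed_sum, ex$score)
  expect_equal(ex$rules$weight, c(0.7, -0.5))  # ordered by |weight|

  # no active rules -> score equals the bias
  ex0 <- explain_subject(m, c(0.1, 0.9))
  expect_equal(ex0$score, -0.1)

  # truncation flag and displayed sum
  ex1 <- explain_subject(m, c(0.9, 0.1), top_k = 1)
  expect_true(ex1$truncated)
  expect_equal(ex1$score, 0.7 - 0.5 - 0.1)
  expect_equal(ex1$displayed_sum, 0.7 - 0.1)

  expect_error(explain_subject(m, c(1, 2, 3)), "features")
})

test_that("explanations of fitted models sum active weights to the score", {
  g <- separable_dataset(n = 80, p = 3, seed = 41, bins = 5)
  m <- fit_rules(g$data, fit_config(C = 4, d = 0.4, bins = 5))
  for (i in c(1, 10, 40)) {
    ex <- explain_subject(m, g$data$X[i, ], top_k = 100)
    expect_identical(ex$score, predict(m, g$data$X[i, , drop = FALSE])[1])
    expect_equal(sum(ex$rules$contribution) + ex$bias, ex$score)
  }
})

test_that("intersection-matrix layout orders rows by feature, columns by weight", {
  r1 <- conjunction_rule(1L, 0.2, 0.8)
  r2 <- conjunction_rule(c(1L, 3L), c(-Inf, 0.1), c(0.5, Inf))
  r3 <- conjunction_rule(2L, 0.4, Inf)
  m <- make_toy_model(list(r1, r2, r3), c(0.3, -0.9, 0.6), 0.05, p = 3)
  exs <- list(explain_subject(m, c(0.5, 0.5, 0.5)))
  path <- file.path(tempdir(), "imatrix.png")
  layout <- suppressWarnings(render_intersection_matrix(exs, m, path))

  expect_equal(layout$rows, m$feature_names)
  expect_equal(layout$columns, c("R1", "R2", "R3"))
  expect_equal(layout$importance, c(0.9, 0.6, 0.3))
  expect_equal(layout$weights, c(-0.9, 0.6, 0.3))
  # sidecar JSON written and parseable
  side <- jsonlite::read_json(paste0(path, ".layout.json"),
                              simplifyVector = TRUE)
  expect_equal(side$rows, m$feature_names)
  expect_equal(nrow(side$cells), 3 * 3)
  # most important rule (r2) touches x1 and x3 but not x2
  expect_false(subset(layout$cells, rule == 1 & feature == "x2")$selected)
  expect_true(subset(layout$cells, rule == 1 & feature == "x1")$selected)
  expect_true(subset(layout$cells, rule == 1 & feature == "x3")$selected)
})

test_that("cross-validation is stratified, deterministic, and accurate on separable data", {
  g <- separable_dataset(n = 120, p = 3, seed = 51, bins = 4)
  cfg <- fit_config(C = 4, d = 0.5, bins = 4)
  r1 <- cv_evaluate(g$data, cfg, folds = 3, repeats = 2, seed = 6)
  r2 <- cv_evaluate(g$data, cfg, folds = 3, repeats = 2, seed = 6)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$per_fold), 6L)
  acc <- r1$summary$mean[r1$summary$metric == "ACC"]
  expect_gt(acc, 0.95)
  expect_error(cv_evaluate(g$data, cfg, folds = 200), "stratification")
})

test_that("holdout evaluation keeps the stratified split honest", {
  g <- separable_dataset(n = 90, p = 3, seed = 61, bins = 4)
  hv <- holdout_evaluate(g$data, fit_config(C = 4, bins = 4), seed = 3)
  expect_gt(hv$metrics$ACC, 0.9)
  expect_equal(hv$metrics$n_classified + hv$metrics$n_rejected,
               length(hv$test_index))
  expect_lt(length(hv$test_index), 90 * 0.5)
})
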