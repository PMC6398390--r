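test_that("double hinge matches its piecewise definition and validates d", {
  expect_equal(double_hinge(1.2, 0.3), 0)
  expect_equal(double_hinge(0, 0.25), 1)
  expect_equal(double_hinge(-1, 0.4), 2.5)      # 1 - (0.6/0.4) * (-1)
  expect_equal(double_hinge(0.5, 0.5), 0.5)
  expect_error(double_hinge(0, 0), "d must")
  expect_error(double_hinge(0, 0.6), "d must")
})

test_that("loss is nonincreasing and steeper below zero for smaller d", {
  z <- seq(-3, 3, by = 0.01)
  for (d in c(0.5, 0.48, 0.4, 0.2)) {
    v <- double_hinge(z, d)
    expect_true(all(diff(v) <= 1e-12))
  }
  zneg <- -1.5
  slopes <- vapply(c(0.5, 0.4, 0.3, 0.2), function(d)
    (double_hinge(zneg, d) - double_hinge(zneg + 1e-4, d)) / 1e-4, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("bias-only master matches an exhaustive grid-search oracle", {
  y <- c(1, 1, 1, -1, -1)
  for (d in c(0.5, 0.3)) {
    cfg <- fit_config(C = 1.3, d = d)
    s <- solve_master(matrix(0, 5, 0), y, cfg)
    expect_equal(s$objective, bias_only_optimum(y, cfg), tolerance = 1e-3)
  }
})

test_that("a perfectly separating column gets positive weight and zero loss", {
  y <- c(1, 1, -1, -1)
  H <- matrix(c(1, 1, 0, 0), 4, 1)
  cfg <- fit_config(C = 100, d = 0.5)
  s <- solve_master(H, y, cfg)
  expect_gt(s$weights[1], 0)
  f <- H %*% s$weights + s$bias
  expect_true(all(y * f >= 1 - 1e-9))  # zero double-hinge loss
  expect_equal(s$objective, sum(abs(s$weights)), tolerance = 1e-9)
})

test_that("duplicating a column leaves the optimum unchanged", {
  set.seed(7)
  inst <- random_instance(n = 18, p = 3)
  H <- inst$trans$incidence[, c(2, 5, 8)] * 1
  cfg <- fit_config(C = 2, d = 0.4)
  s1 <- solve_master(H, inst$y, cfg)
  s2 <- solve_master(cbind(H, H[, 1]), inst$y, cfg)
  expect_equal(s2$objective, s1$objective, tolerance = 1e-8)
})

test_that("master solutions satisfy strong duality and dual feasibility", {
  set.seed(31)
  for (trial in 1:8) {
    inst <- random_instance(n = sample(10:25, 1), p = sample(2:4, 1))
    m <- min(6L, ncol(inst$trans$incidence))
    H <- inst$trans$incidence[, sample(ncol(inst$trans$incidence), m)] * 1
    cfg <- fit_config(C = stats::runif(1, 0.5, 3),
                      d = stats::runif(1, 0.2, 0.5))
    s <- solve_master(H, inst$y, cfg)
    k <- (1 - cfg$d) / cfg$d
    C_i <- ifelse(inst$y == 1, cfg$C * length(inst$y) / (2 * sum(inst$y == 1)),
                  cfg$C * length(inst$y) / (2 * sum(inst$y == -1)))
    # primal value recomputed from the loss definition
    f <- H %*% s$weights + s$bias
    primal <- sum(abs(s$weights)) + sum(C_i * double_hinge(inst$y * f, cfg$d))
    expect_equal(primal, s$objective, tolerance = 1e-7)
    # strong duality: dual objective (sum of constraint duals) equals primal
    expect_equal(sum(s$alpha), s$objective, tolerance = 1e-7)
    # dual feasibility on supplied columns, bias constraint, box bound
    expect_lte(max(abs(t(H) %*% (inst$y * s$u))), 1 + 1e-7)
    expect_lt(abs(sum(inst$y * s$u)), 1e-7)
    expect_lte(max(s$u - k * C_i), 1e-7)
    expect_gte(min(s$u), -1e-12)
  }
})

test_that("pricing oracle equals brute-force enumeration", {
  set.seed(99)
  for (trial in 1:25) {
    inst <- random_instance(n = sample(8:30, 1), p = sample(2:4, 1))
    u <- stats::runif(length(inst$y), 0, 3)
    r <- find_best_rule(inst$trans, inst$y, u, max_order = 3, tolerance = -1)
    got <- if (is.null(r)) 0 else r$gain
    expect_equal(got,
                 brute_force_best_gain(inst$trans$incidence, inst$y * u, 3),
                 tolerance = 1e-9)
  }
  # all-zero duals price nothing
  inst <- random_instance(n = 10, p = 2)
  expect_null(find_best_rule(inst$trans, inst$y, rep(0, 10), 3))
})

test_that("column generation reaches the full-enumeration optimum on tiny data", {
  set.seed(55)
  for (trial in 1:5) {
    inst <- random_instance(n = sample(10:25, 1), p = sample(2:3, 1))
    cfg <- fit_config(C = 1.5, d = 0.4, bins = 3, max_rule_order = 2)
    dat <- rule_dataset(inst$X, inst$y)
    m <- fit_rules(dat, cfg)
    Hfull <- enumerate_all_columns(inst$trans$incidence, 2)
    full <- solve_master(Hfull, inst$y, cfg)
    expect_equal(m$objective, full$objective, tolerance = 1e-6)
  }
})

test_that("fitting recovers a planted separable rule with zero training error", {
  g <- separable_dataset(n = 200, p = 5)
  m <- fit_rules(g$data, fit_config(C = 10, d = 0.5, bins = 8))
  f <- predict(m, g$data$X)
  expect_equal(mean(sign(f) != g$data$y), 0)
  # top rule boundary within one bin of the planted threshold 0.5
  top <- m$rules[[which.max(abs(m$weights))]]
  cc <- m$cutpoints$cuts[[1]]
  binw <- max(diff(c(0, cc, 1)))
  bnd <- c(top$lo, top$hi)
  expect_true(any(abs(bnd[is.finite(bnd)] - 0.5) <= binw))
})

test_that("objective trajectory is nonincreasing and matches direct evaluation", {
  g <- separable_dataset(n = 80, p = 3, seed = 5, bins = 4)
  m <- fit_rules(g$data, fit_config(C = 2, d = 0.4, bins = 4))
  expect_true(all(diff(m$trajectory) <= 1e-6))
  expect_equal(model_objective(m, g$data), m$objective, tolerance = 1e-6)
})

test_that("degenerate fits are rejected or trivial as specified", {
  g <- separable_dataset(n = 40, p = 2, seed = 3)
  m0 <- fit_rules(g$data, fit_config(max_iterations = 0))
  expect_length(m0$rules, 0)

  d_const <- rule_dataset(matrix(5, 10, 2), rep(c(1, -1), 5))
  expect_error(fit_rules(d_const), "constant")

  d_one <- rule_dataset(matrix(stats::runif(20), 10, 2), rep(1, 10))
  expect_error(fit_rules(d_one), "both classes")
})

test_that("empty model objective equals the total weighted unit loss", {
  y <- c(1, 1, -1)
  dat <- rule_dataset(matrix(stats::runif(6), 3, 2), y)
  cfg <- fit_config(C_pos = 2, C_neg = 3, d = 0.4)
  m <- make_toy_model(list(), numeric(0), 0)
  m$config <- cfg
  expect_equal(model_objective(m, dat), 2 * 2 + 3 * 1)  # phi(0) = 1
})
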