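# Independent oracles and small fixture builders used across the suite.

# exhaustive enumeration of the pricing problem: best |weighted cover sum|
# over all itemsets of size <= max_order with nonempty cover
brute_force_best_gain <- function(incidence, w, max_order) {
  m <- ncol(incidence)
  best <- 0
  for (k in seq_len(min(max_order, m))) {
    cmb <- utils::combn(m, k)
    for (j in seq_len(ncol(cmb))) {
      cov <- rowSums(!incidence[, cmb[, j], drop = FALSE]) == 0
      if (any(cov)) best <- max(best, abs(sum(w[cov])))
    }
  }
  best
}

# all itemsets up to max_order materialised as 0/1 activation columns
# (full-enumeration master problem)
enumerate_all_columns <- function(incidence, max_order) {
  m <- ncol(incidence)
  cols <- list()
  for (k in seq_len(min(max_order, m))) {
    cmb <- utils::combn(m, k)
    for (j in seq_len(ncol(cmb))) {
      act <- as.integer(rowSums(!incidence[, cmb[, j], drop = FALSE]) == 0)
      if (any(act == 1L)) cols[[length(cols) + 1L]] <- act
    }
  }
  if (length(cols) == 0L) return(matrix(0, nrow(incidence), 0))
  do.call(cbind, cols)
}

# random small classification instance with both classes guaranteed
random_instance <- function(n, p, bins = 3L) {
  X <- matrix(stats::runif(n * p), n, p)
  y <- sample(c(-1, 1), n, replace = TRUE)
  if (!any(y == 1)) y[1] <- 1
  if (!any(y == -1)) y[2] <- -1
  cuts <- build_cutpoints(X, bins)
  list(X = X, y = y, cuts = cuts, trans = build_transactions(X, cuts))
}

# exhaustive bias-only optimum of the double-hinge objective
bias_only_optimum <- function(y, cfg, grid = seq(-5, 5, by = 0.001)) {
  C_i <- ifelse(y == 1,
                if (!is.null(cfg$C_pos)) cfg$C_pos
                else cfg$C * length(y) / (2 * sum(y == 1)),
                if (!is.null(cfg$C_neg)) cfg$C_neg
                else cfg$C * length(y) / (2 * sum(y == -1)))
  min(vapply(grid, function(b) sum(C_i * double_hinge(y * b, cfg$d)),
             numeric(1)))
}

# fully specified hand-made model, bypassing the fitting path
make_toy_model <- function(rules, weights, bias, p = NULL,
                           feature_names = NULL) {
  if (is.null(p))
    p <- max(1L, max(unlist(lapply(rules, function(r) r$feature)), 0L))
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(p))
  cuts <- structure(list(cuts = rep(list(numeric(0)), p), bins = 10L,
                         feature_names = feature_names),
                    class = "cutpoint_table")
  structure(list(rules = rules, weights = weights, bias = bias,
                 cutpoints = cuts, config = fit_config(),
                 C_pos = 1, C_neg = 1, objective = NA_real_,
                 trajectory = numeric(0), iterations = 0L,
                 converged = TRUE, stalled = FALSE,
                 feature_names = feature_names),
            class = "rule_model")
}

# a small planted-rule dataset a sparse fit can separate exactly: the
# planted threshold is placed on the quantile grid the learner will build,
# so the discretised rule space contains the labelling rule itself
separable_dataset <- function(n = 120L, p = 4L, seed = 11L, bins = 8L) {
  set.seed(seed)
  X <- matrix(stats::runif(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  cc <- build_cutpoints(X, bins)$cuts[[1]]
  thr <- cc[which.min(abs(cc - 0.5))]
  rule <- conjunction_rule(1L, thr, Inf)
  y <- ifelse(rule_matches(rule, X) == 1L, 1, -1)
  list(data = rule_dataset(X, y),
       truth = list(rules = list(rule), weights = 2, intercept = -1,
                    clean_labels = y, flipped = rep(FALSE, n)))
}
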