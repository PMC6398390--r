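#' Fit configuration
#'
#' Hyperparameters of the sparse rule-ensemble fit. Misclassification costs
#' may be given explicitly (`C_pos`, `C_neg`); by default they are derived
#' from the single knob `C` with inverse class-frequency balancing,
#' `C_pos = C * n / (2 n_pos)` and `C_neg = C * n / (2 n_neg)`, so the two
#' classes contribute comparably under imbalance.
#'
#' @param C overall misclassification cost (positive real).
#' @param C_pos,C_neg explicit per-class costs; override `C` when supplied.
#' @param d rejection cost in (0, 0.5]; at `d = 0.5` the surrogate loss is
#'   the ordinary hinge. Smaller `d` penalises confidently wrong margins
#'   more steeply.
#' @param max_rule_order maximum number of items (interval conditions) per
#'   rule.
#' @param max_iterations cap on column-generation rounds; each round adds at
#'   most one rule.
#' @param bins discretisation bins per feature (see [build_cutpoints()]).
#' @param pricing_tolerance slack on the dual constraint: fitting stops when
#'   no itemset has gain above `1 + pricing_tolerance`.
#' @param lp_tolerance numerical tolerance of the master linear program.
#' @param calibration_folds default fold count for [calibrate()].
#' @param seed integer seed used by calibration and evaluation helpers.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(C = 1, C_pos = NULL, C_neg = NULL, d = 0.4,
                       max_rule_order = 3L, max_iterations = 100L,
                       bins = 10L, pricing_tolerance = 1e-6,
                       lp_tolerance = 1e-6, calibration_folds = 5L,
                       seed = 1L) {
  if (d <= 0 || d > 0.5) stop("rejection cost d must lie in (0, 0.5]")
  if (C <= 0) stop("C must be positive")
  if (!is.null(C_pos) && C_pos <= 0) stop("C_pos must be positive")
  if (!is.null(C_neg) && C_neg <= 0) stop("C_neg must be positive")
  if (max_rule_order < 1L) stop("max_rule_order must be >= 1")
  if (max_iterations < 0L) stop("max_iterations must be >= 0")
  structure(list(C = C, C_pos = C_pos, C_neg = C_neg, d = d,
                 max_rule_order = as.integer(max_rule_order),
                 max_iterations = as.integer(max_iterations),
                 bins = as.integer(bins),
                 pricing_tolerance = pricing_tolerance,
                 lp_tolerance = lp_tolerance,
                 calibration_folds = as.integer(calibration_folds),
                 seed = as.integer(seed)),
            class = "fit_config")
}

resolve_costs <- function(cfg, y) {
  n_pos <- sum(y == 1); n_neg <- sum(y == -1)
  C_pos <- if (!is.null(cfg$C_pos)) cfg$C_pos
           else cfg$C * length(y) / (2 * n_pos)
  C_neg <- if (!is.null(cfg$C_neg)) cfg$C_neg
           else cfg$C * length(y) / (2 * n_neg)
  list(C_pos = C_pos, C_neg = C_neg,
       C_i = ifelse(y == 1, C_pos, C_neg))
}

#' Double-hinge surrogate loss
#'
#' Piecewise-linear convex loss `max(0, 1 - z, 1 - z (1 - d) / d)` of the
#' margin `z`: zero for `z >= 1`, unit slope on `[0, 1)`, and slope
#' `(1 - d)/d` for negative margins. The kink structure is what makes a
#' minimiser support an abstain region; at `d = 0.5` it coincides with the
#' ordinary hinge loss.
#'
#' @param z numeric margin values.
#' @param d rejection cost in (0, 0.5].
#' @return nonnegative loss values, vectorised over `z`.
#' @export
double_hinge <- function(z, d) {
  if (d <= 0 || d > 0.5) stop("rejection cost d must lie in (0, 0.5]")
  pmax(0, 1 - z, 1 - ((1 - d) / d) * z)
}

#' L1-penalised empirical objective of a rule model
#'
#' Direct evaluation of the training objective: the sum of absolute rule
#' weights plus the class-weighted double-hinge losses of the per-sample
#' margins `y_i f(x_i)`. This routine shares no code with the linear
#' program that minimises the same quantity, so the two serve as mutual
#' checks.
#'
#' @param model a `rule_model`.
#' @param data a `rule_dataset`.
#' @param cfg optional `fit_config`; defaults to the configuration stored
#'   in the model.
#' @return scalar objective value.
#' @export
model_objective <- function(model, data, cfg = NULL) {
  stopifnot(inherits(model, "rule_model"), inherits(data, "rule_dataset"))
  if (is.null(cfg)) cfg <- model$config
  costs <- resolve_costs(cfg, data$y)
  f <- predict(model, data$X)
  loss <- double_hinge(data$y * f, cfg$d)
  sum(abs(model$weights)) + sum(costs$C_i * loss)
}

#' Solve the restricted master linear program
#'
#' Minimises the L1-penalised double-hinge objective over the supplied rule
#' columns by primal simplex. Returns primal weights and bias together with
#' the per-sample dual mining weights `u_i` that drive the pricing search:
#' at the optimum every supplied column j satisfies
#' `|sum_i y_i u_i h_j(x_i)| <= 1` (up to tolerance).
#'
#' @param H n x m matrix of 0/1 rule activations (one column per candidate
#'   rule; `m = 0` gives the bias-only model).
#' @param y labels in \{+1, -1\}, both classes present.
#' @param cfg a `fit_config`.
#' @return list with `weights`, `bias`, `xi` (slacks), `objective`,
#'   `u` (mining weights), `alpha` (raw constraint duals), `pivots`.
#' @export
solve_master <- function(H, y, cfg = fit_config()) {
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  if (!any(y == 1) || !any(y == -1)) stop("both classes must be present")
  H <- as.matrix(H)
  if (length(H) == 0L) H <- matrix(0, length(y), 0L)
  if (nrow(H) != length(y)) stop("nrow(H) must equal length(y)")
  costs <- resolve_costs(cfg, y)
  k <- (1 - cfg$d) / cfg$d
  lp <- .lp_create(y, k, costs$C_i)
  for (j in seq_len(ncol(H)))
    .lp_add_column(lp, as.integer(H[, j] != 0))
  .lp_solve(lp)
}

#' Find the most violated rule column (pricing oracle)
#'
#' Branch-and-bound search over interval itemsets of order at most
#' `max_order` for the one maximising `|sum_{i in cover} y_i u_i|`. The
#' search prunes with the anti-monotone bound `max(sum of positive terms,
#' -sum of negative terms)` over the current cover and is exact: the
#' returned gain equals the enumeration maximum.
#'
#' @param transactions a `transaction_matrix`.
#' @param y labels in \{+1, -1\}.
#' @param u nonnegative per-sample dual weights from [solve_master()].
#' @param max_order maximum itemset size.
#' @param tolerance violation slack; `NULL` is returned when the best gain
#'   is at most `1 + tolerance` (no dual constraint is violated).
#' @return `NULL`, or a list with `items` (catalogue rows), `rule` (the
#'   reduced `conjunction_rule`), `gain`, and `activation` (0/1 vector).
#' @export
find_best_rule <- function(transactions, y, u, max_order = 3L,
                           tolerance = 1e-6) {
  stopifnot(inherits(transactions, "transaction_matrix"))
  inc <- transactions$incidence
  if (length(u) != nrow(inc)) stop("duals misaligned with transactions")
  if (ncol(inc) == 0L) return(NULL)
  w <- as.numeric(y) * as.numeric(u)
  res <- .mine_best_itemset(inc, w, as.integer(transactions$items$feature),
                            as.integer(transactions$items$direction == "GEQ"),
                            as.integer(max_order))
  if (length(res$items) == 0L || res$gain <= 1 + tolerance) return(NULL)
  items <- transactions$items[res$items, , drop = FALSE]
  act <- as.integer(rowSums(!inc[, res$items, drop = FALSE]) == 0L)
  list(items = items, rule = reduce_itemset(items), gain = res$gain,
       activation = act)
}

#' Fit a sparse interval-rule ensemble by column generation
#'
#' Starting from the bias-only master problem, alternates between solving
#' the restricted linear program and mining the rule whose dual constraint
#' is most violated, adding one rule column per round. Because the pricing
#' search is exact, the procedure terminates at the global optimum of the
#' full (exponentially large) rule-space problem when no violated column
#' remains.
#'
#' @param data a `rule_dataset` with both classes present.
#' @param config a `fit_config`.
#' @return object of class `rule_model`: `rules` (list of
#'   `conjunction_rule`s with nonzero weight), `weights`, `bias`,
#'   `cutpoints`, `config`, `objective`, `trajectory` (objective after each
#'   master solve), `iterations`, `converged` (TRUE when pricing found no
#'   violated column), `stalled` (TRUE when rounds stopped improving the
#'   objective), `feature_names`.
#' @export
fit_rules <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "rule_dataset"))
  if (!any(data$y == 1) || !any(data$y == -1))
    stop("cannot fit: both classes must be present")
  cuts <- build_cutpoints(data$X, config$bins)
  trans <- build_transactions(data$X, cuts)
  if (ncol(trans$incidence) == 0L)
    stop("cannot fit: all features are constant (no candidate intervals)")

  costs <- resolve_costs(config, data$y)
  k <- (1 - config$d) / config$d
  lp <- .lp_create(data$y, k, costs$C_i)
  sol <- .lp_solve(lp)
  trajectory <- sol$objective

  gen_items <- list()
  gen_keys <- character(0)
  converged <- FALSE
  stalled <- FALSE
  stall_run <- 0L
  iter <- 0L
  while (iter < config$max_iterations) {
    best <- find_best_rule(trans, data$y, sol$u,
                           max_order = config$max_rule_order,
                           tolerance = config$pricing_tolerance)
    if (is.null(best)) { converged <- TRUE; break }
    key <- paste(best$items$feature, best$items$direction,
                 best$items$threshold, collapse = "|")
    if (key %in% gen_keys) break  # numerical stall guard
    gen_keys <- c(gen_keys, key)
    gen_items[[length(gen_items) + 1L]] <- best$items
    .lp_add_column(lp, best$activation)
    prev_obj <- sol$objective
    sol <- .lp_solve(lp)
    trajectory <- c(trajectory, sol$objective)
    iter <- iter + 1L
    # dual degeneracy can price marginally violated columns that leave the
    # primal objective unchanged; a long run of such rounds means the
    # solution has effectively converged
    if (prev_obj - sol$objective < config$lp_tolerance) {
      stall_run <- stall_run + 1L
      if (stall_run >= 15L) { stalled <- TRUE; break }
    } else stall_run <- 0L
  }

  keep <- which(abs(sol$weights) > 1e-9)
  rules <- lapply(gen_items[keep], reduce_itemset)
  model <- structure(list(
    rules = rules,
    weights = as.numeric(sol$weights[keep]),
    bias = sol$bias,
    cutpoints = cuts,
    config = config,
    C_pos = costs$C_pos, C_neg = costs$C_neg,
    objective = sol$objective,
    trajectory = trajectory,
    iterations = iter,
    converged = converged,
    stalled = stalled,
    feature_names = data$feature_names
  ), class = "rule_model")
  model
}

#' Predict scores from a rule model
#'
#' The decision function is the weighted sum of rule activations plus the
#' bias: `f(x) = sum_j a_j h_j(x) + b`.
#'
#' @param object a `rule_model`.
#' @param newdata numeric matrix, data frame, or `rule_dataset`.
#' @param ... unused.
#' @return numeric score vector.
#' @export
predict.rule_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "rule_dataset")) newdata$X else as.matrix(newdata)
  s <- rep(object$bias, nrow(X))
  for (j in seq_along(object$rules))
    s <- s + object$weights[j] * rule_matches(object$rules[[j]], X)
  s
}

#' @export
print.rule_model <- function(x, ...) {
  cat("Sparse interval-rule ensemble\n")
  cat(sprintf("  %d rules, bias %.4g, objective %.6g (%s after %d rounds)\n",
              length(x$rules), x$bias, x$objective,
              if (x$converged) "converged" else "iteration cap",
              x$iterations))
  o <- order(-abs(x$weights))
  for (j in o)
    cat(sprintf("  %+0.4f  %s\n", x$weights[j],
                format(x$rules[[j]], feature_names = x$feature_names)))
  invisible(x)
}
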