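#' Two-stage screening cost policy
#'
#' Describes a triage design in which every subject receives the cheap
#' stage-1 assay (e.g. a plasma panel) and only subjects the stage-1
#' classifier rejects are referred to the expensive stage-2 assay (e.g.
#' CSF). Costs are abstract units.
#'
#' @param stages two stage names.
#' @param unit_costs nonnegative per-screening cost of each stage.
#' @return object of class `cost_policy`.
#' @export
cost_policy <- function(stages = c("plasma", "csf"), unit_costs = c(1, 10)) {
  if (length(stages) != 2L || length(unit_costs) != 2L)
    stop("exactly two stages are supported")
  if (any(unit_costs < 0)) stop("unit costs must be nonnegative")
  structure(list(stages = as.character(stages),
                 unit_costs = as.numeric(unit_costs)),
            class = "cost_policy")
}

#' Evaluate a screening policy's cost and correctness
#'
#' Two-stage mode (`stage2_decisions` supplied): every subject pays the
#' stage-1 unit cost; subjects rejected at stage 1 are referred and pay the
#' stage-2 unit cost as well, and their final decision is the stage-2 one.
#' Single-stage mode (`stage2_decisions = NULL`): the stage-1 decision is
#' final and each subject pays only the stage-1 cost. Rejections at the
#' final stage count as not correct and are flagged.
#'
#' @param stage1_decisions vector over \{+1, 0, -1\}.
#' @param stage2_decisions decisions for (at least) the stage-1 rejects;
#'   `NA` allowed for non-referred subjects. `NULL` for single-stage.
#' @param y true labels in \{+1, -1\}.
#' @param policy a `cost_policy`.
#' @return object of class `policy_evaluation`: `total_cost`, `n_correct`,
#'   `n_screened` (per stage), `n_final_rejects`, and an `outcomes` data
#'   frame (per-subject stage decisions, final decision, cost, correct).
#' @export
evaluate_policy <- function(stage1_decisions, stage2_decisions, y, policy) {
  stopifnot(inherits(policy, "cost_policy"))
  n <- length(y)
  if (length(stage1_decisions) != n)
    stop("stage-1 decisions misaligned with labels")
  c1 <- policy$unit_costs[1]; c2 <- policy$unit_costs[2]
  referred <- stage1_decisions == 0L
  if (is.null(stage2_decisions)) {
    final <- stage1_decisions
    cost <- rep(c1, n)
    screened2 <- 0L
  } else {
    if (length(stage2_decisions) != n)
      stop("stage-2 decisions misaligned with labels")
    if (any(referred & is.na(stage2_decisions)))
      stop("incomplete policy: a referred subject has no stage-2 decision")
    final <- stage1_decisions
    final[referred] <- stage2_decisions[referred]
    cost <- rep(c1, n) + ifelse(referred, c2, 0)
    screened2 <- sum(referred)
  }
  correct <- final == y  # final rejects (0) never equal a +1/-1 label
  outcomes <- data.frame(
    stage1 = stage1_decisions,
    stage2 = if (is.null(stage2_decisions)) rep(NA_integer_, n)
             else ifelse(referred, stage2_decisions, NA_integer_),
    final = final, y = y, cost = cost, correct = correct)
  structure(list(
    total_cost = sum(cost),
    n_correct = sum(correct),
    n_screened = stats::setNames(c(n, screened2), policy$stages),
    n_final_rejects = sum(final == 0L),
    policy = policy,
    outcomes = outcomes
  ), class = "policy_evaluation")
}

#' @export
print.policy_evaluation <- function(x, ...) {
  cat(sprintf("Screening policy: %s", paste(names(x$n_screened)[x$n_screened > 0],
                                            collapse = " -> ")), "\n")
  cat(sprintf("  screened: %s\n",
              paste(sprintf("%s %d", names(x$n_screened), x$n_screened),
                    collapse = ", ")))
  cat(sprintf("  total cost %.5g units, %d/%d correct, %d unresolved\n",
              x$total_cost, x$n_correct, nrow(x$outcomes), x$n_final_rejects))
  invisible(x)
}

#' Rank screening policies by correctness and cost
#'
#' @param evaluations named list of `policy_evaluation` objects computed on
#'   the same subjects.
#' @param y true labels (consistency check).
#' @return data frame sorted by descending `n_correct`, then ascending
#'   `total_cost`; ties keep input order.
#' @export
compare_policies <- function(evaluations, y) {
  stopifnot(length(evaluations) >= 1L)
  if (is.null(names(evaluations)))
    names(evaluations) <- paste0("policy", seq_along(evaluations))
  for (ev in evaluations) {
    stopifnot(inherits(ev, "policy_evaluation"))
    if (nrow(ev$outcomes) != length(y))
      stop("all policies must be evaluated on the same samples")
  }
  tab <- data.frame(
    policy = names(evaluations),
    n_correct = vapply(evaluations, function(e) e$n_correct, numeric(1)),
    total_cost = vapply(evaluations, function(e) e$total_cost, numeric(1)),
    n_final_rejects = vapply(evaluations, function(e) e$n_final_rejects,
                             numeric(1)))
  tab <- tab[order(-tab$n_correct, tab$total_cost, seq_len(nrow(tab))), ]
  rownames(tab) <- NULL
  tab
}
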