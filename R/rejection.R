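#' @keywords internal
make_stratified_folds <- function(y, folds, seed) {
  if (folds < 2L) stop("folds must be >= 2")
  if (min(sum(y == 1), sum(y == -1)) < folds)
    stop("stratification error: a class has fewer samples than folds")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in c(-1, 1)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# weighted pool-adjacent-violators on (x, y, w) already unique/sorted in x;
# returns fitted values (nondecreasing). stats::isoreg has no weights, and
# tied scores must be pooled for the map to be a function of the score,
# hence this small exact solver (cross-checked against isoreg on tie-free
# data in the test suite).
#' @keywords internal
pav_weighted <- function(y, w) {
  n <- length(y)
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top] + 1e-15) {
      tw <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (val[top - 1L] * wt[top - 1L] + val[top] * wt[top]) / tw
      wt[top - 1L] <- tw
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], sz[seq_len(top)])
}

#' Isotonic regression of labels on scores
#'
#' Pools tied scores, then fits a monotone nondecreasing step sequence by
#' pool-adjacent-violators.
#'
#' @param scores numeric scores.
#' @param labels numeric targets (typically 0/1 class indicators).
#' @return list with sorted unique `x` and fitted nondecreasing `y`.
#' @export
isotonic_fit <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  o <- order(scores)
  x <- scores[o]; y <- labels[o]
  ux <- unique(x)
  grp <- match(x, ux)
  w <- tabulate(grp, nbins = length(ux))
  ybar <- as.numeric(rowsum(y, grp)) / w
  list(x = ux, y = pav_weighted(ybar, w))
}

#' Calibrate a rule model to posterior probabilities
#'
#' Produces out-of-fold scores by refitting the ensemble on each stratified
#' fold complement with the model's own configuration, then fits an
#' isotonic (monotone nondecreasing, piecewise-linear interpolated) map
#' from score to the posterior probability of the positive class. Using
#' out-of-fold rather than training scores avoids the optimistic bias of
#' in-sample margins. The map is clipped to `[1e-6, 1 - 1e-6]` and extended
#' by constants beyond the fitted score range.
#'
#' @param model a fitted `rule_model`.
#' @param data the `rule_dataset` to calibrate on.
#' @param folds number of stratified folds (>= 2); defaults to the model
#'   configuration's `calibration_folds`.
#' @param seed fold-assignment seed; defaults to the configuration seed.
#' @return object of class `calibrated_model` with elements `base`,
#'   `calibration` (breakpoints `x`, `y`), `folds`, `seed`.
#' @export
calibrate <- function(model, data, folds = NULL, seed = NULL) {
  stopifnot(inherits(model, "rule_model"), inherits(data, "rule_dataset"))
  if (is.null(folds)) folds <- model$config$calibration_folds
  if (is.null(seed)) seed <- model$config$seed
  fold <- make_stratified_folds(data$y, folds, seed)
  oof <- numeric(length(data$y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    sub <- rule_dataset(data$X[tr, , drop = FALSE], data$y[tr],
                        feature_names = data$feature_names)
    m_f <- fit_rules(sub, model$config)
    oof[!tr] <- predict(m_f, data$X[!tr, , drop = FALSE])
  }
  iso <- isotonic_fit(oof, as.numeric(data$y == 1))
  eps <- 1e-6
  iso$y <- pmin(pmax(iso$y, eps), 1 - eps)
  structure(list(base = model, calibration = iso,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "calibrated_model")
}

#' Map raw scores through a fitted calibration
#'
#' @param cal calibration breakpoints (list with `x`, `y`).
#' @param s numeric scores.
#' @return posterior probabilities in `[1e-6, 1 - 1e-6]`.
#' @keywords internal
apply_calibration <- function(cal, s) {
  if (length(cal$x) == 1L) return(rep(cal$y, length(s)))
  stats::approx(cal$x, cal$y, xout = s, rule = 2, ties = "ordered")$y
}

#' Predict from a calibrated model
#'
#' @param object a `calibrated_model`.
#' @param newdata matrix, data frame, or `rule_dataset`.
#' @param type `"eta"` for posterior probabilities, `"score"` for raw
#'   scores, `"decision"` for the minimum-expected-cost +1/0/-1 decisions.
#' @param d rejection cost used when `type = "decision"`; defaults to the
#'   fit configuration's `d`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.calibrated_model <- function(object, newdata,
                                     type = c("eta", "score", "decision"),
                                     d = NULL, ...) {
  type <- match.arg(type)
  s <- predict(object$base, newdata)
  if (type == "score") return(s)
  eta <- apply_calibration(object$calibration, s)
  if (type == "eta") return(eta)
  if (is.null(d)) d <- object$base$config$d
  decide(eta, d)
}

#' Minimum-expected-cost decision with a reject option
#'
#' With unit misclassification cost and rejection cost `d`, the decision
#' minimising expected cost given the posterior `eta = P(y = +1 | x)` is:
#' +1 when `eta > 1 - d`, -1 when `eta < d`, and reject (0) when
#' `d <= eta <= 1 - d` (boundaries reject).
#'
#' @param eta posterior probabilities in `[0, 1]`.
#' @param d rejection cost in (0, 0.5].
#' @return integer vector over \{+1, 0, -1\}.
#' @export
decide <- function(eta, d) {
  if (d <= 0 || d > 0.5) stop("rejection cost d must lie in (0, 0.5]")
  if (any(eta < 0 | eta > 1)) stop("eta must lie in [0, 1]")
  ifelse(eta > 1 - d, 1L, ifelse(eta < d, -1L, 0L))
}

#' Decisions at a target rejection rate
#'
#' Rejects the `round(target_rr * n)` samples whose posterior is closest
#' to 1/2 (ties broken by sample order) and classifies the rest by
#' thresholding at 1/2. This sweeps the symmetric rejection band
#' empirically instead of through the loss parameter `d`.
#'
#' @param eta posterior probabilities.
#' @param target_rr requested rejection rate in `[0, 1)`.
#' @return list with `decisions` (+1/0/-1), `achieved_rr`, and `band`
#'   (the posterior interval actually rejected).
#' @export
decide_at_rejection_rate <- function(eta, target_rr) {
  if (target_rr < 0 || target_rr >= 1)
    stop("target rejection rate must lie in [0, 1)")
  n <- length(eta)
  if (n == 0L) stop("eta must be nonempty")
  n_rej <- floor(target_rr * n + 0.5)  # nearest achievable count
  dec <- ifelse(eta > 0.5, 1L, -1L)
  band <- c(0.5, 0.5)
  if (n_rej > 0L) {
    ord <- order(abs(eta - 0.5), seq_len(n))
    rej <- ord[seq_len(n_rej)]
    dec[rej] <- 0L
    half <- max(abs(eta[rej] - 0.5))
    band <- c(0.5 - half, 0.5 + half)
  }
  list(decisions = dec, achieved_rr = n_rej / n, band = band)
}

#' Rank-based AUC (ties get half credit)
#'
#' @param scores numeric scores.
#' @param y labels in \{+1, -1\}.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
rank_auc <- function(scores, y) {
  pos <- y == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics on the non-rejected subset
#'
#' Sensitivity, specificity and accuracy are computed over classified
#' samples only; rejected samples enter only the rejection rate. AUC is
#' computed from the posteriors of the classified subset when supplied.
#'
#' @param decisions vector over \{+1, 0, -1\}.
#' @param y true labels in \{+1, -1\}.
#' @param eta optional posteriors for AUC.
#' @return object of class `rejection_metrics`: `RR`, `ACC`, `SN`, `SP`,
#'   `AUC`, `n_classified`, `n_rejected`, `TP`, `FP`, `TN`, `FN`.
#' @export
rejection_metrics <- function(decisions, y, eta = NULL) {
  stopifnot(length(decisions) == length(y))
  cls <- decisions != 0L
  if (!any(cls)) stop("metrics undefined: every sample was rejected")
  d <- decisions[cls]; yy <- y[cls]
  TP <- sum(d == 1 & yy == 1); FP <- sum(d == 1 & yy == -1)
  TN <- sum(d == -1 & yy == -1); FN <- sum(d == -1 & yy == 1)
  auc <- if (is.null(eta)) NA_real_ else rank_auc(eta[cls], yy)
  structure(list(
    RR = mean(!cls),
    ACC = (TP + TN) / sum(cls),
    SN = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    SP = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    AUC = auc,
    n_classified = sum(cls), n_rejected = sum(!cls),
    TP = TP, FP = FP, TN = TN, FN = FN
  ), class = "rejection_metrics")
}

#' @export
print.rejection_metrics <- function(x, ...) {
  cat(sprintf(
    "RR %.3f | ACC %.3f SN %.3f SP %.3f AUC %s | classified %d rejected %d\n",
    x$RR, x$ACC, x$SN, x$SP,
    if (is.na(x$AUC)) "NA" else sprintf("%.3f", x$AUC),
    x$n_classified, x$n_rejected))
  invisible(x)
}

#' Accuracy-rejection trade-off curve
#'
#' Applies [decide_at_rejection_rate()] along a grid of target rejection
#' rates. Because rejection is by distance of the posterior from 1/2, the
#' classified subsets are nested as the rate increases.
#'
#' @param eta posterior probabilities.
#' @param y true labels in \{+1, -1\}.
#' @param rr_grid rejection rates in `[0, 1)`.
#' @return data frame with columns `RR` (target), `achieved_RR`, `ACC`,
#'   `AUC`, `n_classified`, `n_rejected`, `TP`, `FP`, `TN`, `FN`.
#' @export
accuracy_rejection_curve <- function(eta, y,
                                     rr_grid = seq(0, 0.5, by = 0.05)) {
  rows <- lapply(rr_grid, function(rr) {
    dd <- decide_at_rejection_rate(eta, rr)
    m <- rejection_metrics(dd$decisions, y, eta)
    data.frame(RR = rr, achieved_RR = dd$achieved_rr, ACC = m$ACC,
               AUC = m$AUC, n_classified = m$n_classified,
               n_rejected = m$n_rejected, TP = m$TP, FP = m$FP,
               TN = m$TN, FN = m$FN)
  })
  do.call(rbind, rows)
}
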