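MODEL_FORMAT_VERSION <- "1"

inf_to_na <- function(v) ifelse(is.finite(v), v, NA_real_)

# JSON null -> +/-Inf; handles scalars, vectors, lists with NULL holes,
# and a bare null collapsed to NULL on read (hence the explicit length)
na_to_inf <- function(v, sign, len) {
  v <- as.list(v)
  if (length(v) == 0L) v <- vector("list", len)
  v <- vapply(v, function(z)
    if (is.null(z) || is.na(z)) NA_real_ else as.numeric(z), numeric(1))
  ifelse(is.na(v), sign * Inf, v)
}

#' Save a fitted model to a JSON file
#'
#' The model file is a human-auditable JSON document holding the cutpoint
#' table, the rules as per-feature intervals, weights, bias, the fit
#' configuration, calibration breakpoints (if calibrated) and provenance.
#' Numbers are written at full precision so a reloaded model predicts
#' bitwise-identically.
#'
#' @param model a `rule_model` or `calibrated_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  cal <- NULL
  base <- model
  if (inherits(model, "calibrated_model")) {
    cal <- list(x = model$calibration$x, y = model$calibration$y,
                folds = model$folds, seed = model$seed)
    base <- model$base
  } else if (!inherits(model, "rule_model")) {
    stop("model must be a rule_model or calibrated_model")
  }
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    type = if (is.null(cal)) "rule_model" else "calibrated_model",
    cutpoints = list(cuts = base$cutpoints$cuts,
                     bins = base$cutpoints$bins,
                     feature_names = base$cutpoints$feature_names),
    rules = lapply(base$rules, function(r)
      list(feature = r$feature, lo = inf_to_na(r$lo), hi = inf_to_na(r$hi))),
    weights = base$weights,
    bias = base$bias,
    config = unclass(base$config),
    C_pos = base$C_pos, C_neg = base$C_neg,
    objective = base$objective,
    trajectory = base$trajectory,
    iterations = base$iterations,
    converged = base$converged,
    stalled = isTRUE(base$stalled),
    feature_names = base$feature_names,
    calibration = cal,
    provenance = list(package = "rulereject",
                      version = as.character(utils::packageVersion("rulereject")),
                      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                      seed = base$config$seed,
                      n_features = length(base$feature_names))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Load a model file written by `save_model()`
#'
#' @param path JSON model file.
#' @return a `rule_model` or `calibrated_model`, predicting identically to
#'   the saved object.
#' @export
load_model <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE),
    error = function(e) stop("cannot parse model file '", path, "': ",
                             conditionMessage(e)))
  if (is.null(doc$format_version) ||
      !identical(as.character(doc$format_version), MODEL_FORMAT_VERSION))
    stop("unsupported model format version: ",
         if (is.null(doc$format_version)) "<missing>" else doc$format_version)
  cuts <- structure(list(
    cuts = lapply(doc$cutpoints$cuts, as.numeric),
    bins = as.integer(doc$cutpoints$bins),
    feature_names = as.character(doc$cutpoints$feature_names)
  ), class = "cutpoint_table")
  rules <- lapply(doc$rules, function(r) {
    feat <- as.integer(unlist(r$feature))
    conjunction_rule(feat,
                     na_to_inf(r$lo, -1, length(feat)),
                     na_to_inf(r$hi, +1, length(feat)))
  })
  cfgl <- doc$config
  cfg <- fit_config(C = cfgl$C, C_pos = cfgl$C_pos, C_neg = cfgl$C_neg,
                    d = cfgl$d, max_rule_order = cfgl$max_rule_order,
                    max_iterations = cfgl$max_iterations, bins = cfgl$bins,
                    pricing_tolerance = cfgl$pricing_tolerance,
                    lp_tolerance = cfgl$lp_tolerance,
                    calibration_folds = cfgl$calibration_folds,
                    seed = cfgl$seed)
  base <- structure(list(
    rules = rules, weights = as.numeric(doc$weights), bias = doc$bias,
    cutpoints = cuts, config = cfg, C_pos = doc$C_pos, C_neg = doc$C_neg,
    objective = doc$objective, trajectory = as.numeric(doc$trajectory),
    iterations = doc$iterations, converged = doc$converged,
    stalled = isTRUE(doc$stalled),
    feature_names = as.character(doc$feature_names)
  ), class = "rule_model")
  if (identical(doc$type, "rule_model")) return(base)
  structure(list(base = base,
                 calibration = list(x = as.numeric(doc$calibration$x),
                                    y = as.numeric(doc$calibration$y)),
                 folds = as.integer(doc$calibration$folds),
                 seed = as.integer(doc$calibration$seed)),
            class = "calibrated_model")
}

#' Explain one subject's score
#'
#' Decomposes the model score as the sum of the weights of the rules the
#' subject activates plus the bias, and reports each rule's intervals next
#' to the subject's feature values. When fewer rules are displayed than the
#' model holds (`top_k` truncation) the displayed-sum may differ from the
#' full score and the truncation is flagged.
#'
#' @param model a `rule_model` or `calibrated_model`.
#' @param x numeric feature vector for one subject.
#' @param top_k number of rules (by decreasing absolute weight) to display.
#' @return object of class `rule_explanation` with `rules` data frame
#'   (`rank`, `weight`, `active`, `contribution`, `displayed`, `text`),
#'   `bias`, `score`, `displayed_sum`, `truncated`, and — for calibrated
#'   models — `eta` and `decision`.
#' @export
explain_subject <- function(model, x, top_k = 10L) {
  if (top_k < 1L) stop("top_k must be >= 1")
  base <- if (inherits(model, "calibrated_model")) model$base else model
  stopifnot(inherits(base, "rule_model"))
  x <- as.numeric(x)
  if (length(x) != length(base$feature_names))
    stop("x has ", length(x), " features but the model expects ",
         length(base$feature_names))
  nr <- length(base$rules)
  act <- vapply(base$rules, evaluate_rule, integer(1), x = x)
  contrib <- base$weights * act
  score <- sum(contrib) + base$bias
  o <- order(-abs(base$weights))
  displayed <- seq_len(nr) %in% o[seq_len(min(top_k, nr))]
  tab <- data.frame(
    rank = match(seq_len(nr), o),
    weight = base$weights,
    active = act,
    contribution = contrib,
    displayed = displayed,
    text = vapply(base$rules, format, character(1),
                  feature_names = base$feature_names))
  tab <- tab[o, ]
  rownames(tab) <- NULL
  out <- list(rules = tab, bias = base$bias, score = score,
              displayed_sum = sum(contrib[displayed]) + base$bias,
              truncated = top_k < nr,
              x = stats::setNames(x, base$feature_names),
              feature_names = base$feature_names)
  if (inherits(model, "calibrated_model")) {
    out$eta <- apply_calibration(model$calibration, score)
    out$decision <- decide(out$eta, base$config$d)
  }
  structure(out, class = "rule_explanation")
}

#' @export
print.rule_explanation <- function(x, ...) {
  cat(sprintf("Model score %.4g = bias %.4g + active rule weights\n",
              x$score, x$bias))
  shown <- x$rules[x$rules$displayed, ]
  for (i in seq_len(nrow(shown)))
    cat(sprintf("  [%s] %+0.4f  %s\n",
                if (shown$active[i]) "x" else " ", shown$weight[i],
                shown$text[i]))
  if (x$truncated)
    cat(sprintf("  (truncated: displayed sum %.4g may differ from score)\n",
                x$displayed_sum))
  if (!is.null(x$eta))
    cat(sprintf("  posterior %.3f -> decision %+d\n", x$eta, x$decision))
  invisible(x)
}

#' Intersection-matrix layout and figure
#'
#' Renders the fitted rule set as an intersection matrix: one row per
#' feature, one column per rule (sorted by decreasing absolute weight),
#' each cell marking the interval the rule selects on that feature, with
#' per-rule importance bars and per-subject value markers. The structured
#' layout is written as a JSON sidecar (`<path>.layout.json`) and is the
#' contract the test suite checks; the figure itself is cosmetic.
#'
#' @param explanations list of `rule_explanation`s from one model (the
#'   first defines the rule set; each contributes a subject marker).
#' @param model the `rule_model` (or `calibrated_model`) the explanations
#'   came from.
#' @param path image output path (`.png` or `.svg`); the layout sidecar is
#'   written next to it.
#' @return the layout list, invisibly.
#' @export
render_intersection_matrix <- function(explanations, model, path) {
  if (length(explanations) < 1L) stop("need at least one explanation")
  base <- if (inherits(model, "calibrated_model")) model$base else model
  o <- order(-abs(base$weights))
  feats <- base$feature_names
  # feature context range: span of the cut grid, padded by one bin width
  frange <- lapply(seq_along(feats), function(j) {
    cc <- base$cutpoints$cuts[[j]]
    if (length(cc) == 0L) return(c(0, 1))
    pad <- if (length(cc) > 1L) min(diff(cc)) else max(abs(cc[1]), 1) * 0.1
    c(min(cc) - pad, max(cc) + pad)
  })
  cells <- list()
  for (cidx in seq_along(o)) {
    r <- base$rules[[o[cidx]]]
    for (j in seq_along(feats)) {
      sel <- j %in% r$feature
      lo <- hi <- NA_real_
      if (sel) {
        jj <- match(j, r$feature)
        lo <- max(r$lo[jj], frange[[j]][1])
        hi <- min(r$hi[jj], frange[[j]][2])
      }
      cells[[length(cells) + 1L]] <-
        data.frame(rule = cidx, feature = feats[j], selected = sel,
                   lo = lo, hi = hi)
    }
  }
  cells <- do.call(rbind, cells)
  layout <- list(
    rows = feats,
    columns = paste0("R", seq_along(o)),
    importance = abs(base$weights)[o],
    weights = base$weights[o],
    bias = base$bias,
    cells = cells,
    subjects = lapply(explanations, function(e)
      list(values = as.list(e$x), score = e$score))
  )
  jsonlite::write_json(layout, paste0(path, ".layout.json"),
                       auto_unbox = TRUE, digits = I(17), na = "null",
                       pretty = TRUE)

  df <- cells
  df$feature <- factor(df$feature, levels = rev(feats))
  df$flo <- vapply(as.character(df$feature), function(f)
    frange[[match(f, feats)]][1], numeric(1))
  df$fhi <- vapply(as.character(df$feature), function(f)
    frange[[match(f, feats)]][2], numeric(1))
  df$x0 <- ifelse(df$selected, (df$lo - df$flo) / (df$fhi - df$flo), NA)
  df$x1 <- ifelse(df$selected, (df$hi - df$flo) / (df$fhi - df$flo), NA)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_tile(
      ggplot2::aes(x = .data$rule, y = .data$feature,
                   fill = .data$selected),
      colour = "grey40", width = 0.95, height = 0.95) +
    ggplot2::geom_segment(
      data = df[df$selected, ],
      ggplot2::aes(x = .data$rule - 0.45 + 0.9 * .data$x0,
                   xend = .data$rule - 0.45 + 0.9 * .data$x1,
                   y = as.numeric(.data$feature),
                   yend = as.numeric(.data$feature)),
      linewidth = 2, colour = "darkred") +
    ggplot2::scale_fill_manual(
      values = c("TRUE" = "mistyrose", "FALSE" = "honeydew"),
      guide = "none") +
    ggplot2::scale_x_continuous(
      breaks = seq_along(o),
      labels = sprintf("R%d\n(%+.2f)", seq_along(o), base$weights[o])) +
    ggplot2::labs(x = "rule (by importance)", y = NULL,
                  title = "Intersection matrix: selected intervals per rule") +
    ggplot2::theme_minimal()
  ok <- try(suppressMessages(ggplot2::ggsave(
    path, p, width = 2 + length(o), height = 1 + 0.4 * length(feats),
    limitsize = FALSE)), silent = TRUE)
  if (inherits(ok, "try-error"))
    warning("figure device unavailable; layout sidecar written to ",
            paste0(path, ".layout.json"))
  invisible(layout)
}

#' Repeated stratified cross-validation
#'
#' Fits the ensemble on each fold complement, scores the held-out fold,
#' and aggregates sensitivity, specificity, accuracy, and AUC at zero
#' rejection (decisions by the sign of the score) over folds x repeats.
#' Fold assignments reshuffle per repeat from the seed.
#'
#' @param data a `rule_dataset`.
#' @param config a `fit_config`.
#' @param folds number of stratified folds.
#' @param repeats number of repetitions.
#' @param seed base seed; repeat `r` uses `seed + r - 1`.
#' @return list with `summary` (data frame of mean and sd per metric) and
#'   `per_fold` (one row per fold x repeat).
#' @export
cv_evaluate <- function(data, config = fit_config(), folds = 5L,
                        repeats = 10L, seed = 1L) {
  stopifnot(inherits(data, "rule_dataset"))
  if (folds < 2L) stop("folds must be >= 2")
  if (repeats < 1L) stop("repeats must be >= 1")
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    fold <- make_stratified_folds(data$y, folds, seed + rep_i - 1L)
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- fit_rules(rule_dataset(data$X[tr, , drop = FALSE], data$y[tr],
                                  feature_names = data$feature_names),
                     config)
      s <- predict(m, data$X[!tr, , drop = FALSE])
      dec <- ifelse(s > 0, 1L, -1L)
      yte <- data$y[!tr]
      met <- rejection_metrics(dec, yte)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_i = rep_i, fold = f, SN = met$SN, SP = met$SP,
        ACC = met$ACC, AUC = rank_auc(s, yte))
    }
  }
  per_fold <- do.call(rbind, rows)
  metr <- c("SN", "SP", "ACC", "AUC")
  summary <- data.frame(
    metric = metr,
    mean = vapply(metr, function(m) mean(per_fold[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metr, function(m) stats::sd(per_fold[[m]], na.rm = TRUE),
                numeric(1)))
  rownames(summary) <- NULL
  list(summary = summary, per_fold = per_fold)
}

#' Single stratified train/test split evaluation
#'
#' Splits the data into stratified train and test parts (default 2/3 vs
#' 1/3), fits on the training part, and reports test metrics at zero
#' rejection.
#'
#' @param data a `rule_dataset`.
#' @param config a `fit_config`.
#' @param train_fraction fraction used for training.
#' @param seed split seed.
#' @return list with `metrics` (a `rejection_metrics`), `auc`, `model`,
#'   and the test index vector.
#' @export
holdout_evaluate <- function(data, config = fit_config(),
                             train_fraction = 2 / 3, seed = 1L) {
  stopifnot(inherits(data, "rule_dataset"))
  set.seed(seed)
  tr_idx <- unlist(lapply(c(-1, 1), function(cl) {
    idx <- which(data$y == cl)
    sample(idx, max(1L, round(train_fraction * length(idx))))
  }))
  tr <- seq_along(data$y) %in% tr_idx
  if (!any(!tr)) stop("train fraction leaves no test samples")
  m <- fit_rules(rule_dataset(data$X[tr, , drop = FALSE], data$y[tr],
                              feature_names = data$feature_names), config)
  s <- predict(m, data$X[!tr, , drop = FALSE])
  yte <- data$y[!tr]
  met <- rejection_metrics(ifelse(s > 0, 1L, -1L), yte)
  list(metrics = met, auc = rank_auc(s, yte), model = m,
       test_index = which(!tr))
}
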