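#' Construct a labelled dataset for rule fitting
#'
#' Bundles a numeric feature matrix with labels coded +1 (positive class,
#' e.g. disease) and -1 (negative class). Missing values are rejected:
#' imputation, if needed, is the caller's responsibility.
#'
#' @param X numeric matrix or data frame, samples in rows.
#' @param y labels; either already in \{+1, -1\} or coercible via
#'   `positive_label`.
#' @param feature_names optional character vector, defaults to the column
#'   names of `X`.
#' @param positive_label if supplied, labels equal to it become +1 and all
#'   others -1.
#' @return an object of class `rule_dataset` with elements `X`, `y`,
#'   `feature_names`.
#' @export
rule_dataset <- function(X, y, feature_names = NULL, positive_label = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least two samples")
  if (ncol(X) < 1L) stop("need at least one feature")
  if (anyNA(X)) stop("X contains missing values; impute before loading")
  if (!is.null(positive_label)) {
    y <- ifelse(y == positive_label, 1, -1)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(y) || !all(y %in% c(-1, 1)))
    stop("labels must be +1/-1 (or use positive_label to map them)")
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    if (is.null(feature_names))
      feature_names <- paste0("x", seq_len(ncol(X)))
  }
  colnames(X) <- feature_names
  structure(list(X = X, y = y, feature_names = feature_names),
            class = "rule_dataset")
}

#' Read a delimited feature table into a `rule_dataset`
#'
#' @param path CSV or TSV file with a header row.
#' @param label_col name of the label column.
#' @param positive_label value in `label_col` mapped to +1; everything else
#'   becomes -1.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (".tsv"/".txt" means tab, otherwise comma).
#' @return a `rule_dataset`.
#' @export
read_dataset <- function(path, label_col, positive_label, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_col %in% names(df))
    stop("label column '", label_col, "' not found in ", path)
  y <- df[[label_col]]
  X <- df[setdiff(names(df), label_col)]
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all feature columns must be numeric")
  rule_dataset(as.matrix(X), y, positive_label = positive_label)
}

#' Quantile cutpoints for feature discretisation
#'
#' Each continuous feature is divided into at most `bins` intervals at its
#' interior empirical quantiles. Duplicate quantiles (heavily tied values)
#' are merged, and constant features get an empty cut list.
#'
#' @param X numeric feature matrix.
#' @param bins number of intervals per feature (at least 2); cuts are the
#'   `bins - 1` interior quantiles.
#' @return a `cutpoint_table`: list with `cuts` (one sorted numeric vector
#'   per feature), `bins`, and `feature_names`.
#' @export
build_cutpoints <- function(X, bins = 10L) {
  X <- as.matrix(X)
  if (bins < 2L) stop("bins must be >= 2")
  probs <- seq_len(bins - 1L) / bins
  cuts <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    if (max(x) == min(x)) return(numeric(0))
    unname(sort(unique(stats::quantile(x, probs = probs, type = 7))))
  })
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  structure(list(cuts = cuts, bins = as.integer(bins), feature_names = nm),
            class = "cutpoint_table")
}

#' Item catalogue of a cutpoint table
#'
#' Every cut `c` on feature `j` spawns two one-dimensional interval items:
#' `x_j <= c` and `x_j >= c`. The catalogue order — feature index, then
#' direction with LEQ before GEQ, then threshold ascending — is the
#' deterministic tie-break order used throughout the package.
#'
#' @param cuts a `cutpoint_table`.
#' @return data frame with columns `feature` (integer index), `direction`
#'   ("LEQ"/"GEQ") and `threshold`.
#' @export
item_catalogue <- function(cuts) {
  stopifnot(inherits(cuts, "cutpoint_table"))
  parts <- lapply(seq_along(cuts$cuts), function(j) {
    cc <- cuts$cuts[[j]]
    if (length(cc) == 0L)
      return(data.frame(feature = integer(0), direction = character(0),
                        threshold = numeric(0)))
    data.frame(feature = j,
               direction = rep(c("LEQ", "GEQ"), each = length(cc)),
               threshold = c(cc, cc))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Binary transaction matrix over interval items
#'
#' Evaluates every catalogue item on every sample: sample `i` "contains"
#' item `(j, LEQ, c)` iff `X[i, j] <= c` (and `>=` for GEQ; a value exactly
#' at a cut satisfies both directions).
#'
#' @param X numeric feature matrix with the same column count the cutpoints
#'   were built from.
#' @param cuts a `cutpoint_table`.
#' @return list of class `transaction_matrix` with `incidence` (n x m
#'   logical matrix) and `items` (the catalogue data frame).
#' @export
build_transactions <- function(X, cuts) {
  X <- as.matrix(X)
  stopifnot(inherits(cuts, "cutpoint_table"))
  if (ncol(X) != length(cuts$cuts))
    stop("X has ", ncol(X), " columns but cutpoints were built for ",
         length(cuts$cuts))
  items <- item_catalogue(cuts)
  m <- nrow(items)
  inc <- matrix(FALSE, nrow(X), m)
  for (kk in seq_len(m)) {
    xj <- X[, items$feature[kk]]
    inc[, kk] <- if (items$direction[kk] == "LEQ")
      xj <= items$threshold[kk] else xj >= items$threshold[kk]
  }
  structure(list(incidence = inc, items = items),
            class = "transaction_matrix")
}

#' Conjunction rule over per-feature closed intervals
#'
#' A conjunction rule is a product of one-dimensional interval indicators,
#' e.g. I(1.0 <= x3 <= 2.0) I(x5 >= 0.5); it fires (returns 1) iff every
#' interval contains the corresponding feature value. Bounds are closed on
#' both sides; `-Inf`/`Inf` mark one-sided intervals.
#'
#' @param feature integer feature indices (one interval per feature).
#' @param lo,hi numeric lower/upper bounds, same length as `feature`.
#' @return object of class `conjunction_rule`.
#' @export
conjunction_rule <- function(feature, lo, hi) {
  stopifnot(length(feature) == length(lo), length(lo) == length(hi))
  if (anyDuplicated(feature)) stop("at most one interval per feature")
  if (any(lo > hi)) stop("empty interval: lo > hi")
  o <- order(feature)
  structure(list(feature = as.integer(feature)[o], lo = as.numeric(lo)[o],
                 hi = as.numeric(hi)[o]),
            class = "conjunction_rule")
}

#' @export
format.conjunction_rule <- function(x, feature_names = NULL, ...) {
  if (length(x$feature) == 0L) return("I(TRUE)")
  nm <- if (is.null(feature_names)) paste0("x", x$feature)
        else feature_names[x$feature]
  term <- function(j) {
    if (is.finite(x$lo[j]) && is.finite(x$hi[j]))
      sprintf("I(%.4g <= %s <= %.4g)", x$lo[j], nm[j], x$hi[j])
    else if (is.finite(x$lo[j]))
      sprintf("I(%s >= %.4g)", nm[j], x$lo[j])
    else
      sprintf("I(%s <= %.4g)", nm[j], x$hi[j])
  }
  paste(vapply(seq_along(x$feature), term, character(1)), collapse = " ")
}

#' @export
print.conjunction_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Evaluate a conjunction rule on one sample
#'
#' @param rule a `conjunction_rule`.
#' @param x numeric feature vector.
#' @return 1 if every interval holds (an empty rule always fires), else 0.
#' @export
evaluate_rule <- function(rule, x) {
  stopifnot(inherits(rule, "conjunction_rule"))
  if (length(rule$feature) == 0L) return(1L)
  if (max(rule$feature) > length(x))
    stop("rule references feature ", max(rule$feature),
         " but x has only ", length(x))
  v <- x[rule$feature]
  as.integer(all(v >= rule$lo & v <= rule$hi))
}

#' Evaluate a conjunction rule on every row of a matrix
#'
#' @param rule a `conjunction_rule`.
#' @param X numeric feature matrix.
#' @return integer 0/1 vector of length `nrow(X)`.
#' @export
rule_matches <- function(rule, X) {
  X <- as.matrix(X)
  if (length(rule$feature) == 0L) return(rep(1L, nrow(X)))
  if (max(rule$feature) > ncol(X))
    stop("rule references feature ", max(rule$feature),
         " but X has only ", ncol(X))
  ok <- rep(TRUE, nrow(X))
  for (j in seq_along(rule$feature)) {
    v <- X[, rule$feature[j]]
    ok <- ok & v >= rule$lo[j] & v <= rule$hi[j]
  }
  as.integer(ok)
}

#' Reduce an itemset to a conjunction rule
#'
#' Per feature, the lower bound is the largest GEQ threshold and the upper
#' bound the smallest LEQ threshold among the items. Contradictory bounds
#' (lo > hi) make the conjunction unsatisfiable and `NULL` is returned.
#'
#' @param items data frame with columns `feature`, `direction`, `threshold`
#'   (rows of an item catalogue).
#' @return a `conjunction_rule`, or `NULL` for an empty (unsatisfiable)
#'   conjunction.
#' @export
reduce_itemset <- function(items) {
  if (nrow(items) == 0L)
    return(conjunction_rule(integer(0), numeric(0), numeric(0)))
  feats <- sort(unique(items$feature))
  lo <- hi <- numeric(length(feats))
  for (j in seq_along(feats)) {
    sub <- items[items$feature == feats[j], ]
    g <- sub$threshold[sub$direction == "GEQ"]
    l <- sub$threshold[sub$direction == "LEQ"]
    lo[j] <- if (length(g)) max(g) else -Inf
    hi[j] <- if (length(l)) min(l) else Inf
    if (lo[j] > hi[j]) return(NULL)
  }
  conjunction_rule(feats, lo, hi)
}
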