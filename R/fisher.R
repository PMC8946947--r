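#' Fisher score ranking of features
#'
#' Filter-method feature scoring for a two-class table: for feature r,
#' `F_r = sum_c n_c (mu_rc - mu_r)^2 / sum_c n_c sigma2_rc`
#' with population (divide-by-n) class variances. A zero denominator with a
#' nonzero numerator scores `+Inf` (the feature separates the classes
#' perfectly within each class); 0/0 scores 0. Ranking ties are broken by
#' original column order, so the ordering is deterministic.
#'
#' @param table data frame with a `class` column (exactly 2 levels, each
#'   with at least 2 subjects) and numeric feature columns; columns named
#'   `subject_id`/`class` are excluded from scoring.
#' @param variance `"population"` (default) or `"sample"` class variances.
#' @return list of class `iron_fisher`: `scores` (named, in column order)
#'   and `order` (feature names by descending score).
#' @export
fisher_score <- function(table, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  cls <- as.character(table$class)
  levels <- unique(cls)
  if (length(levels) != 2)
    stop("Fisher scoring requires exactly 2 classes, got ", length(levels))
  if (any(tabulate(factor(cls)) < 2))
    stop("each class needs at least 2 subjects")
  feats <- setdiff(names(table), c("subject_id", "class"))
  X <- as.matrix(table[, feats, drop = FALSE])
  if (!is.numeric(X)) stop("feature columns must be numeric")
  if (any(!is.finite(X))) stop("feature table contains non-finite values")
  n <- nrow(X)
  mu <- colMeans(X)
  num <- den <- numeric(length(feats))
  for (lv in levels) {
    Xi <- X[cls == lv, , drop = FALSE]
    ni <- nrow(Xi)
    mui <- colMeans(Xi)
    vi <- colMeans(sweep(Xi, 2, mui)^2)
    if (variance == "sample") vi <- vi * ni / (ni - 1)
    num <- num + ni * (mui - mu)^2
    den <- den + ni * vi
  }
  scores <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  names(scores) <- feats
  ord <- feats[order(-scores)]       # stable: ties keep column order
  structure(list(scores = scores, order = ord), class = "iron_fisher")
}

#' @export
print.iron_fisher <- function(x, ...) {
  cat("<iron_fisher> top features:\n")
  print(utils::head(x$scores[x$order], 10))
  invisible(x)
}

#' Select the top-k Fisher-ranked features
#'
#' @param ranking an `iron_fisher` from [fisher_score()].
#' @param k number of features (default 10).
#' @return character vector of k feature names, best first.
#' @export
select_top_k <- function(ranking, k = 10) {
  if (k > length(ranking$order))
    stop("k = ", k, " exceeds the number of features (",
         length(ranking$order), ")")
  ranking$order[seq_len(k)]
}
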