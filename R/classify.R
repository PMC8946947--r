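# Repeated stratified-split evaluation harness: splits, metrics, AUC, the
# ten-classifier roster, and the per-task driver.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

#' Stratified train/test split
#'
#' Random partition at the given ratio, stratified by class (per-class
#' train counts are `round(ratio * n_c)`), deterministic per seed.
#'
#' @param table feature table with `subject_id` and `class` columns.
#' @param seed integer seed.
#' @param ratio training fraction (default 0.7).
#' @param stratified stratify by class (default TRUE).
#' @return list of class `iron_split`: `train`, `test` (subject ids),
#'   `seed`, `ratio`, `stratified`.
#' @export
make_split <- function(table, seed, ratio = 0.7, stratified = TRUE) {
  ids <- as.character(table$subject_id)
  cls <- as.character(table$class)
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  train <- character(0)
  with_seed(seed, {
    if (stratified) {
      for (lv in unique(cls)) {
        members <- ids[cls == lv]
        if (length(members) < 2)
          stop("class '", lv, "' too small to stratify")
        n_tr <- round(ratio * length(members))
        n_tr <- min(max(n_tr, 1), length(members) - 1)
        train <- c(train, sample(members, n_tr))
      }
    } else {
      n_tr <- min(max(round(ratio * length(ids)), 1), length(ids) - 1)
      train <- sample(ids, n_tr)
    }
  })
  structure(list(train = sort(train), test = sort(setdiff(ids, train)),
                 seed = seed, ratio = ratio, stratified = stratified),
            class = "iron_split")
}

#' Confusion-count metrics
#'
#' Direct evaluation of sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' balanced accuracy (Sen+Spe)/2, and accuracy (TP+TN)/total. A zero
#' denominator yields `NA` for the affected metric and its name is listed
#' in the `undefined` attribute; it is never silently reported as 0.
#'
#' @param TP,FN,TN,FP non-negative integer confusion counts.
#' @return named numeric vector `Sen`, `Spe`, `bAcc`, `Acc` with attribute
#'   `undefined`.
#' @export
compute_metrics <- function(TP, FN, TN, FP) {
  if (any(c(TP, FN, TN, FP) < 0)) stop("negative confusion count")
  sen <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spe <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  bacc <- if (!is.na(sen) && !is.na(spe)) (sen + spe) / 2 else NA_real_
  total <- TP + TN + FP + FN
  acc <- if (total > 0) (TP + TN) / total else NA_real_
  out <- c(Sen = sen, Spe = spe, bAcc = bacc, Acc = acc)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area over all thresholds, computed through the midrank
#' Mann-Whitney U equivalence (so ties contribute 1/2).
#'
#' @param scores per-subject decision values, higher = more positive.
#' @param labels class labels.
#' @param positive the positive-class label (default: second sorted level).
#' @return scalar AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("AUC needs exactly 2 classes, got ", length(lev))
  if (is.null(positive)) positive <- lev[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

standardizer_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

standardizer_apply <- function(z, X) sweep(sweep(X, 2, z$mu), 2, z$sd, "/")

# --- classifier roster ------------------------------------------------------

adaboost_fit <- function(X, y, rounds = 50) {
  # discrete AdaBoost over depth-1 rpart stumps; y: factor, 2 levels
  n <- nrow(X)
  ypm <- ifelse(y == levels(y)[2], 1, -1)
  w <- rep(1 / n, n)
  df <- data.frame(X, .y = factor(ypm))
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1,
                                                       minsplit = 2,
                                                       cp = -1, xval = 0))
    pred <- as.numeric(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != ypm))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- alpha
    w <- w * exp(-alpha * ypm * pred)
    w <- w / sum(w)
    if (err < 1e-9) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

adaboost_score <- function(model, X) {
  df <- data.frame(X)
  s <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    s <- s + model$alphas[m] *
      as.numeric(as.character(predict(model$stumps[[m]], df, type = "class")))
  }
  s
}

qda_reg_fit <- function(X, y, shrink = c(0, 0.1, 0.5)) {
  for (lam in shrink) {
    fit <- try({
      stats_ <- lapply(levels(y), function(lv) {
        Xi <- X[y == lv, , drop = FALSE]
        S <- stats::cov(Xi)
        S <- (1 - lam) * S + lam * diag(diag(S), ncol(X)) +
          1e-8 * diag(ncol(X))
        ch <- chol(S)
        list(mu = colMeans(Xi), chol = ch,
             logdet = 2 * sum(log(diag(ch))),
             logprior = log(nrow(Xi) / nrow(X)))
      })
      names(stats_) <- levels(y)
      stats_
    }, silent = TRUE)
    if (!inherits(fit, "try-error")) return(list(cls = fit, levels = levels(y)))
  }
  stop("QDA: class covariance not factorizable even with shrinkage")
}

qda_reg_score <- function(model, X) {
  ll <- vapply(model$cls, function(cc) {
    Z <- backsolve(cc$chol, t(sweep(X, 2, cc$mu)), transpose = TRUE)
    -0.5 * colSums(Z^2) - 0.5 * cc$logdet + cc$logprior
  }, numeric(nrow(X)))
  if (is.null(dim(ll))) ll <- matrix(ll, 1)
  ll[, 2] - ll[, 1]   # log-odds of the positive (second) class
}

svm_scores <- function(fit, X, pos) {
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  nm <- strsplit(colnames(dv)[1], "/")[[1]]
  if (nm[1] == pos) dv[, 1] else -dv[, 1]
}

#' The ten-classifier roster
#'
#' kNN, linear SVM, RBF SVM, Gaussian process, random forest, decision
#' tree, multi-layer perceptron, AdaBoost, Gaussian naive Bayes, and
#' quadratic discriminant analysis, each with a small fixed hyperparameter
#' grid searched by cross-validation. Scores are oriented so higher means
#' the positive (second) class; `threshold` is the decision cut for
#' confusion counts.
#'
#' @param names optional subset of classifier names to return.
#' @return named list of classifier definitions.
#' @export
ironmap_classifiers <- function(names = NULL) {
  defs <- list(
    kNN = list(grid = list(list(k = 3), list(k = 5), list(k = 7)),
               threshold = 0.5,
               fit = function(X, y, p)
                 list(X = X, y = y, k = min(p$k, nrow(X))),
               score = function(m, X) {
                 pr <- class::knn(m$X, X, m$y, k = m$k, prob = TRUE)
                 p <- attr(pr, "prob")
                 ifelse(pr == levels(m$y)[2], p, 1 - p)
               }),
    linSVC = list(grid = list(list(cost = 0.1), list(cost = 1),
                              list(cost = 10)),
                  threshold = 0,
                  fit = function(X, y, p)
                    e1071::svm(X, y, kernel = "linear", cost = p$cost,
                               scale = FALSE),
                  score = function(m, X) svm_scores(m, X, levels(m$levels)[2])),
    RBFSVC = list(grid = list(list(cost = 1, gamma = 0.1),
                              list(cost = 10, gamma = 0.1),
                              list(cost = 1, gamma = 1),
                              list(cost = 10, gamma = 1)),
                  threshold = 0,
                  fit = function(X, y, p)
                    e1071::svm(X, y, kernel = "radial", cost = p$cost,
                               gamma = p$gamma / ncol(X), scale = FALSE),
                  score = function(m, X) svm_scores(m, X, levels(m$levels)[2])),
    GP = list(grid = list(list(sigma = 0.05), list(sigma = 0.2)),
              threshold = 0.5,
              fit = function(X, y, p)
                kernlab::gausspr(X, y, kernel = "rbfdot",
                                 kpar = list(sigma = p$sigma),
                                 var = 1, tol = 1e-5, scaled = FALSE),
              score = function(m, X)
                kernlab::predict(m, X, type = "probabilities")[, 2]),
    RF = list(grid = list(list(mtry = 2), list(mtry = 3)),
              threshold = 0.5,
              fit = function(X, y, p)
                randomForest::randomForest(X, y, ntree = 200,
                                           mtry = min(p$mtry, ncol(X))),
              score = function(m, X) predict(m, X, type = "prob")[, 2]),
    DT = list(grid = list(list(cp = 0.01), list(cp = 0.1)),
              threshold = 0.5,
              fit = function(X, y, p)
                rpart::rpart(.y ~ ., data = data.frame(X, .y = y),
                             method = "class",
                             control = rpart::rpart.control(cp = p$cp,
                                                            minsplit = 4,
                                                            minbucket = 2,
                                                            xval = 0)),
              score = function(m, X)
                predict(m, data.frame(X), type = "prob")[, 2]),
    MLP = list(grid = list(list(size = 3), list(size = 5)),
               threshold = 0.5,
               fit = function(X, y, p)
                 nnet::nnet(X, stats::model.matrix(~ y - 1)[, 2],
                            size = p$size, decay = 0.1, maxit = 300,
                            trace = FALSE, entropy = TRUE),
               score = function(m, X) as.numeric(predict(m, X))),
    ADA = list(grid = list(list(rounds = 50)),
               threshold = 0,
               fit = function(X, y, p) adaboost_fit(X, y, p$rounds),
               score = function(m, X) adaboost_score(m, X)),
    GNB = list(grid = list(list()),
               threshold = 0.5,
               fit = function(X, y, p) e1071::naiveBayes(X, y),
               score = function(m, X)
                 predict(m, X, type = "raw")[, 2]),
    QDA = list(grid = list(list(shrink = 0), list(shrink = 0.3)),
               threshold = 0,
               fit = function(X, y, p) qda_reg_fit(X, y, shrink = c(p$shrink, 0.5)),
               score = function(m, X) qda_reg_score(m, X))
  )
  for (nm in names(defs)) defs[[nm]]$name <- nm
  if (!is.null(names)) defs <- defs[names]
  defs
}

fit_classifier <- function(def, X, y, params) {
  m <- def$fit(X, y, params)
  if (inherits(m, "svm")) m$levels <- y
  m
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      i <- which(y == lv)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    fold
  })
}

eval_counts <- function(scores, y, threshold, pos) {
  pred_pos <- scores > threshold
  is_pos <- y == pos
  list(TP = sum(pred_pos & is_pos), FN = sum(!pred_pos & is_pos),
       TN = sum(!pred_pos & !is_pos), FP = sum(pred_pos & !is_pos))
}

metric_row <- function(scores, y, threshold, pos) {
  cc <- eval_counts(scores, y, threshold, pos)
  m <- compute_metrics(cc$TP, cc$FN, cc$TN, cc$FP)
  data.frame(AUC = roc_auc(scores, y, positive = pos),
             bAcc = m["bAcc"], Sen = m["Sen"], Spe = m["Spe"],
             Acc = m["Acc"], TP = cc$TP, FN = cc$FN, TN = cc$TN,
             FP = cc$FP, row.names = NULL)
}

#' Run one pairwise classification task
#'
#' For each repeat: stratified 7:3 split; z-score standardization fit on
#' the training rows; Fisher top-k selection on the training rows; each
#' classifier tuned by stratified 3-fold cross-validation over its grid
#' (best mean out-of-fold AUC, first grid point on ties) and refit on the
#' full training set. Training metrics are the out-of-fold CV metrics at
#' the chosen hyperparameters; test metrics come from the held-out set.
#' Nothing fitted ever reads a test row.
#'
#' @param table cohort feature table (see [extract_cohort()]).
#' @param pair character(2): the two class labels; the second is the
#'   positive class.
#' @param classifiers roster from [ironmap_classifiers()].
#' @param n_repeats number of random split repeats (default 100).
#' @param k_features Fisher top-k (default 10).
#' @param seed master seed; repeat r uses `seed + r`.
#' @param ratio training fraction.
#' @param cv_folds folds for training-side cross-validation.
#' @param tune if `FALSE`, the first grid point is used without search and
#'   CV is only used to estimate training performance.
#' @return list of class `iron_report`: `per_repeat` (one row per repeat x
#'   classifier x split) and `summary` (means and sds over repeats).
#' @export
run_task <- function(table, pair, classifiers = ironmap_classifiers(),
                     n_repeats = 100, k_features = 10, seed = 1,
                     ratio = 0.7, cv_folds = 3, tune = TRUE) {
  stopifnot(length(pair) == 2)
  sub <- table[table$class %in% pair, , drop = FALSE]
  if (length(unique(sub$class)) != 2)
    stop("table does not contain both classes of the pair")
  pos <- pair[2]
  task <- paste(pair, collapse = " vs ")
  rows <- list()
  for (r in seq_len(n_repeats)) {
    rseed <- seed + r
    split <- make_split(sub, seed = rseed, ratio = ratio)
    tr <- sub[sub$subject_id %in% split$train, ]
    te <- sub[sub$subject_id %in% split$test, ]
    ranking <- fisher_score(tr)
    sel_feats <- select_top_k(ranking, k_features)
    Xtr_raw <- as.matrix(tr[, sel_feats, drop = FALSE])
    z <- standardizer_fit(Xtr_raw)
    Xtr <- standardizer_apply(z, Xtr_raw)
    Xte <- standardizer_apply(z, as.matrix(te[, sel_feats, drop = FALSE]))
    ytr <- factor(tr$class, levels = pair)
    yte <- factor(te$class, levels = pair)
    fold <- stratified_folds(ytr, cv_folds, seed = rseed * 13)
    for (tries in 1:10) {
      ok <- all(vapply(seq_len(cv_folds), function(f)
        length(unique(ytr[fold != f])) == 2, logical(1)))
      if (ok) break
      fold <- stratified_folds(ytr, cv_folds, seed = rseed * 13 + tries)
    }
    for (def in classifiers) {
      grid <- if (tune) def$grid else def$grid[1]
      best <- NULL
      for (gi in seq_along(grid)) {
        oof <- rep(NA_real_, nrow(Xtr))
        for (f in seq_len(cv_folds)) {
          use <- fold != f
          m <- with_seed(rseed * 1000 + gi * 10 + f,
                         fit_classifier(def, Xtr[use, , drop = FALSE],
                                        ytr[use], grid[[gi]]))
          oof[!use] <- with_seed(rseed, def$score(m, Xtr[!use, , drop = FALSE]))
        }
        auc <- roc_auc(oof, ytr, positive = pos)
        if (is.null(best) || auc > best$auc)
          best <- list(auc = auc, params = grid[[gi]], oof = oof)
      }
      final <- with_seed(rseed * 1000 + 999,
                         fit_classifier(def, Xtr, ytr, best$params))
      sc_te <- with_seed(rseed, def$score(final, Xte))
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(task = task, classifier = def$name, rep = r,
                   split = c("train", "test"), stringsAsFactors = FALSE),
        rbind(metric_row(best$oof, ytr, def$threshold, pos),
              metric_row(sc_te, yte, def$threshold, pos)))
    }
  }
  per_repeat <- do.call(rbind, rows)
  agg <- stats::aggregate(per_repeat[, c("AUC", "bAcc", "Sen", "Spe", "Acc")],
                          per_repeat[, c("task", "classifier", "split")],
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary <- do.call(data.frame, agg)
  structure(list(per_repeat = per_repeat, summary = summary,
                 pair = pair, seed = seed), class = "iron_report")
}

#' @export
print.iron_report <- function(x, ...) {
  cat("<iron_report>", x$pair[1], "vs", x$pair[2], "\n")
  s <- x$summary[x$summary$split == "test", ]
  s <- s[order(-s$AUC.mean), ]
  print(s[, c("classifier", "AUC.mean", "AUC.sd", "bAcc.mean", "Acc.mean")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
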