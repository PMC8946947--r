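toy_table <- function(seed, n_per_class = 20, p = 10, shift = 0) {
  set.seed(seed)
  n <- 2 * n_per_class
  tab <- data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                    class = rep(c("A", "B"), each = n_per_class),
                    stringsAsFactors = FALSE)
  for (k in seq_len(p)) {
    tab[[paste0("f", k)]] <- rnorm(n) +
      ifelse(tab$class == "B" & k <= 2, shift, 0)
  }
  tab
}

test_that("stratified splits have exact per-class counts and determinism", {
  tab <- toy_table(1, n_per_class = 10)
  s <- make_split(tab, seed = 5, ratio = 0.7)
  cls <- setNames(tab$class, tab$subject_id)
  expect_equal(as.vector(table(cls[s$train])), c(7L, 7L))
  expect_equal(as.vector(table(cls[s$test])), c(3L, 3L))
  expect_setequal(c(s$train, s$test), tab$subject_id)
  expect_identical(make_split(tab, seed = 5), s)
  expect_false(identical(make_split(tab, seed = 6)$train, s$train))
})

test_that("each subject lands in the test set about 30% of the time", {
  tab <- toy_table(2, n_per_class = 10)
  hits <- setNames(numeric(nrow(tab)), tab$subject_id)
  for (seed in 1:100) {
    s <- make_split(tab, seed = seed)
    hits[s$test] <- hits[s$test] + 1
  }
  # binomial(100, 0.3): mean within 4 sd of 30
  expect_true(all(abs(hits - 30) < 4 * sqrt(100 * 0.3 * 0.7)))
})

test_that("confusion metrics equal direct substitution", {
  m <- compute_metrics(TP = 3, FN = 1, TN = 2, FP = 2)
  expect_equal(as.numeric(m), c(0.75, 0.5, 0.625, 0.625))
  perfect <- compute_metrics(TP = 4, FN = 0, TN = 6, FP = 0)
  expect_true(all(perfect == 1))
  allpos <- compute_metrics(TP = 5, FN = 0, TN = 0, FP = 5)
  expect_equal(as.numeric(allpos), c(1, 0, 0.5, 0.5))
  # zero denominator: flagged NA, never a silent 0
  none <- compute_metrics(TP = 0, FN = 0, TN = 3, FP = 1)
  expect_true(is.na(none[["Sen"]]))
  expect_identical(attr(none, "undefined"), c("Sen", "bAcc"))
  expect_error(compute_metrics(-1, 0, 0, 0), "negative")
})

test_that("AUC equals the all-pairs U statistic and its symmetries", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c("A", "A", "A", "B", "B")), 1)
  set.seed(9)
  sc <- round(rnorm(30), 1)   # rounding forces ties
  lb <- sample(c("A", "B"), 30, replace = TRUE, prob = c(0.5, 0.5))
  u <- 0
  for (i in which(lb == "B")) for (j in which(lb == "A"))
    u <- u + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  oracle <- u / (sum(lb == "B") * sum(lb == "A"))
  expect_equal(roc_auc(sc, lb), oracle, tolerance = 1e-12)
  # label inversion flips the area
  expect_equal(roc_auc(sc, lb, positive = "A"), 1 - oracle,
               tolerance = 1e-12)
  # independent library cross-check
  expect_equal(roc_auc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("A", "B"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
  expect_error(roc_auc(sc, rep("A", 30)), "2 classes")
})

test_that("a perfectly separating feature gives test AUC 1 everywhere", {
  tab <- toy_table(3, n_per_class = 12, shift = 10)
  r <- run_task(tab, c("A", "B"), n_repeats = 2, k_features = 5, seed = 4)
  test_rows <- r$summary[r$summary$split == "test", ]
  expect_equal(nrow(test_rows), 10L)   # the full ten-classifier roster
  expect_true(all(test_rows$AUC.mean == 1))
})

test_that("permuted labels give chance-level AUC", {
  tab <- toy_table(5, n_per_class = 15, shift = 3)
  set.seed(99)
  tab$class <- sample(tab$class)
  r <- run_task(tab, c("A", "B"),
                classifiers = ironmap_classifiers(c("RBFSVC", "kNN")),
                n_repeats = 20, k_features = 5, seed = 7)
  aucs <- r$summary$AUC.mean[r$summary$split == "test"]
  expect_true(all(aucs > 0.3 & aucs < 0.7))
})

test_that("the harness is deterministic under a master seed", {
  tab <- toy_table(6, n_per_class = 10, shift = 1)
  r1 <- run_task(tab, c("A", "B"),
                 classifiers = ironmap_classifiers(c("RF", "MLP", "QDA")),
                 n_repeats = 3, k_features = 5, seed = 21)
  r2 <- run_task(tab, c("A", "B"),
                 classifiers = ironmap_classifiers(c("RF", "MLP", "QDA")),
                 n_repeats = 3, k_features = 5, seed = 21)
  expect_identical(r1$per_repeat, r2$per_repeat)
})

test_that("balanced accuracy is exactly the mean of Sen and Spe", {
  tab <- toy_table(7, n_per_class = 10, shift = 1.5)
  r <- run_task(tab, c("A", "B"),
                classifiers = ironmap_classifiers(c("GNB", "DT")),
                n_repeats = 3, k_features = 4, seed = 2)
  pr <- r$per_repeat
  ok <- !is.na(pr$bAcc)
  expect_equal(pr$bAcc[ok], (pr$Sen[ok] + pr$Spe[ok]) / 2, tolerance = 1e-12)
})

test_that("nothing fitted on the training side reads test rows", {
  tab <- toy_table(8, n_per_class = 10, shift = 2)
  r1 <- run_task(tab, c("A", "B"),
                 classifiers = ironmap_classifiers("GNB"),
                 n_repeats = 1, k_features = 5, seed = 31)
  # corrupt the feature values of every held-out subject of the split
  tab2 <- tab
  test_ids <- make_split(tab, seed = 32)$test
  feat_cols <- grep("^f", names(tab2))
  tab2[tab2$subject_id %in% test_ids, feat_cols] <-
    tab2[tab2$subject_id %in% test_ids, feat_cols] + 1000
  r2 <- run_task(tab2, c("A", "B"),
                 classifiers = ironmap_classifiers("GNB"),
                 n_repeats = 1, k_features = 5, seed = 31)
  tr1 <- r1$per_repeat[r1$per_repeat$split == "train", ]
  tr2 <- r2$per_repeat[r2$per_repeat$split == "train", ]
  expect_identical(tr1, tr2)
})
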