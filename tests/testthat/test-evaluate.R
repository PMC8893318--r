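# Metrics against closed forms and brute-force oracles, the inner grid
# search, the mean ROC curve, and the nested cross-validation contract.

test_that("stratified folds balance each class to within one case", {
  y <- rep(c(0L, 1L), each = 64)
  fa <- stratified_folds(y, k = 8L, seed = 1L)
  tabs <- table(fa, y)
  expect_true(all(tabs == 8L))            # 64 per class over 8 folds: exact
  y2 <- c(rep(0L, 65), rep(1L, 60))
  fa2 <- stratified_folds(y2, k = 8L, seed = 2L)
  pos_per_fold <- table(fa2[y2 == 1L])
  expect_true(all(pos_per_fold %in% c(7L, 8L)))
  neg_per_fold <- table(fa2[y2 == 0L])
  expect_true(all(neg_per_fold %in% c(8L, 9L)))
  # deterministic in the seed
  expect_identical(fa, stratified_folds(y, k = 8L, seed = 1L))
  expect_false(identical(fa, stratified_folds(y, k = 8L, seed = 9L)))
  expect_error(stratified_folds(c(rep(0L, 20), rep(1L, 5)), k = 8L, seed = 1L),
               class = "anf_stratification_error")
})

test_that("F2 matches its closed forms", {
  # P = 0.5, R = 1: F2 = 5 * 0.5 / (4 * 0.5 + 1) = 5/6
  expect_equal(f2_score(tp = 2, fp = 2, fn = 0), 5 / 6)
  # P = R = p gives F2 = p
  for (p in c(0.2, 0.5, 0.8)) {
    tp <- 10 * p
    expect_equal(f2_score(tp = tp, fp = 10 - tp, fn = 10 - tp), p)
  }
  expect_equal(f2_score(tp = 0, fp = 0, fn = 3), 0)
  expect_equal(f2_score(tp = 5, fp = 0, fn = 0), 1)
  expect_error(f2_score(tp = 0, fp = 4, fn = 0),
               class = "anf_undefined_metric_error")
})

test_that("AUC equals the pair-counting and trapezoidal oracles", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  set.seed(7)
  for (rep in 1:20) {
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(30), 1)              # rounded scores force ties
    a <- auc_score(y, s)
    expect_equal(a, oracle_auc_pairs(y, s), tolerance = 1e-12)
    expect_equal(a, oracle_auc_trapezoid(y, s), tolerance = 1e-9)
  }
  expect_equal(auc_score(c(0, 1), c(0.2, 0.8)), 1)
  expect_equal(auc_score(c(0, 1), c(0.8, 0.2)), 0)
  expect_error(auc_score(c(1, 1), c(0.1, 0.2)),
               class = "anf_undefined_metric_error")
})

test_that("the metric suite is internally consistent", {
  y <- c(1, 1, 0, 0, 1, 0)
  s <- c(0.9, 0.3, 0.6, 0.1, 0.8, 0.4)
  pred <- as.integer(s >= 0.5)
  ms <- metric_suite(y, pred, s)
  tp <- sum(y == 1 & pred == 1); fp <- sum(y == 0 & pred == 1)
  fn <- sum(y == 1 & pred == 0)
  expect_equal(ms[["precision"]], tp / (tp + fp))
  expect_equal(ms[["recall"]], tp / (tp + fn))
  expect_equal(ms[["f2"]], f2_score(tp, fp, fn), tolerance = 1e-12)
  expect_equal(ms[["acc"]], mean(y == pred))
  # perfect classifier
  perf <- metric_suite(y, y, y)
  expect_equal(unname(perf), c(1, 1, 1, 1, 1))
  # reversing the scores complements the AUC
  expect_equal(metric_suite(y, pred, -s)[["auc"]], 1 - ms[["auc"]])
})

test_that("in-house KNN scores agree with the reference implementation", {
  set.seed(11)
  Xtr <- matrix(rnorm(60 * 3), 60, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  ytr <- rbinom(60, 1, 0.5)
  Xte <- matrix(rnorm(15 * 3), 15, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  fit <- .fit_classifier("knn", Xtr, ytr,
                         data.frame(k = 5, weights = "uniform"), seed = 1L)
  sc <- .predict_score(fit, Xte)
  ref <- class::knn(Xtr, Xte, factor(ytr), k = 5, prob = TRUE)
  pr <- attr(ref, "prob")
  ref_sc <- ifelse(ref == "1", pr, 1 - pr)
  expect_equal(sc, ref_sc, tolerance = 1e-12)
  # distance weighting: a coincident training point dominates
  Xte2 <- Xtr[3, , drop = FALSE] + 1e-13
  fitd <- .fit_classifier("knn", Xtr, ytr,
                          data.frame(k = 7, weights = "distance"), seed = 1L)
  scd <- .predict_score(fitd, Xte2)
  expect_lt(abs(scd - ytr[3]), 1e-4)
})

test_that("inner grid search ranks grid points by mean F2 with first-max ties", {
  tab <- fixture_small_table(n = 56, p = 4, seed = 21)
  std <- standardize(tab)
  X <- std$train$features; y <- tab$labels
  # one-point grid: the winner is that point
  spec1 <- classifier_spec("knn", grid = data.frame(k = 3,
                                                    weights = "uniform",
                                                    stringsAsFactors = FALSE))
  gs1 <- inner_grid_search(spec1, X, y, k_inner = 7L, seed = 5L)
  expect_equal(gs1$best_index, 1L)
  expect_length(gs1$scores, 1L)
  # duplicated grid rows score identically and the FIRST wins the tie
  spec2 <- classifier_spec("knn", grid = data.frame(k = c(3, 3),
                                                    weights = "uniform",
                                                    stringsAsFactors = FALSE))
  gs2 <- inner_grid_search(spec2, X, y, k_inner = 7L, seed = 5L)
  expect_equal(gs2$scores[1], gs2$scores[2])
  expect_equal(gs2$best_index, 1L)
  # exhaustive check: best index attains max of the reported scores
  spec3 <- classifier_spec("knn")
  gs3 <- inner_grid_search(spec3, X, y, k_inner = 7L, seed = 5L)
  expect_equal(gs3$scores[gs3$best_index], max(gs3$scores))
  expect_equal(gs3$best_index, which.max(gs3$scores))
})

test_that("mean ROC interpolation behaves at the extremes", {
  # a perfect fold: TPR jumps to 1 at FPR 0+
  perfect <- list(list(y_true = c(1, 1, 0, 0),
                       y_score = c(0.9, 0.8, 0.2, 0.1)))
  roc <- mean_roc(perfect)
  expect_equal(roc$fpr, seq(0, 1, length.out = 101))
  expect_equal(roc$tpr[1], 0)
  expect_true(all(roc$tpr[-1] == 1))
  # monotone non-decreasing always
  set.seed(3)
  noisy <- lapply(1:4, function(i)
    list(y_true = rbinom(20, 1, 0.5), y_score = runif(20)))
  roc2 <- mean_roc(noisy)
  expect_true(all(diff(roc2$tpr) >= -1e-12))
  expect_equal(roc2$tpr[101], 1)
  # single-class folds are skipped with a warning
  mixed <- c(perfect, list(list(y_true = c(1, 1), y_score = c(0.5, 0.4))))
  expect_warning(roc3 <- mean_roc(mixed), "single-class")
  expect_equal(roc3$tpr, roc$tpr)
  expect_error(suppressWarnings(
    mean_roc(list(list(y_true = c(0, 0), y_score = c(0.1, 0.2))))),
    class = "anf_undefined_metric_error")
})

test_that("nested cross-validation is deterministic and reports per-fold metrics", {
  tab <- fixture_small_table(n = 48, p = 5, seed = 31)
  spec <- classifier_spec("knn", grid = data.frame(k = c(3, 5),
                                                   weights = "uniform",
                                                   stringsAsFactors = FALSE))
  r1 <- nested_cv(tab, spec, seed = 7L, select = FALSE)
  r2 <- nested_cv(tab, spec, seed = 7L, select = FALSE)
  rep1 <- r1$knn
  expect_s3_class(rep1, "cv_report")
  expect_equal(nrow(rep1$folds), 8L)
  expect_identical(rep1$folds, r2$knn$folds)
  expect_equal(rep1$mean$f2, mean(rep1$folds$f2))
  expect_equal(rep1$mean$auc, mean(rep1$folds$auc))
  # strong planted signal: the report should reflect good separation
  expect_gt(rep1$mean$auc, 0.8)
  expect_length(rep1$roc$tpr, 101L)
  expect_length(rep1$hyperparameters, 8L)
})

test_that("held-out folds never influence training (leakage instrumentation)", {
  tab <- fixture_small_table(n = 48, p = 5, seed = 33)
  spec <- classifier_spec("knn", grid = data.frame(k = 3,
                                                   weights = "uniform",
                                                   stringsAsFactors = FALSE))
  fa <- stratified_folds(tab$labels, k = 8L, seed = 7L)
  # perturb the held-out rows of fold 1 and retrain fold 1 manually: the
  # standardizer, the grid search and the fit must be unchanged
  mutated <- tab$features
  mutated[fa == 1L, ] <- mutated[fa == 1L, ] * 100 + 7
  tr <- which(fa != 1L)
  mk <- function(F) feature_table(tab$ids[tr], F[tr, , drop = FALSE],
                                  tab$labels[tr])
  std_a <- standardize(mk(tab$features))
  std_b <- standardize(mk(mutated))
  expect_identical(std_a$center, std_b$center)
  gs_a <- inner_grid_search(spec, std_a$train$features, tab$labels[tr],
                            seed = 17L)
  gs_b <- inner_grid_search(spec, std_b$train$features, tab$labels[tr],
                            seed = 17L)
  expect_identical(gs_a$scores, gs_b$scores)
})

test_that("small cohorts shrink the selection fold count instead of failing", {
  # 8 + 8 cases: outer-training splits hold 7 per class, fewer than the
  # canonical 8 selection folds
  set.seed(51)
  X <- matrix(rnorm(16 * 6), 16, 6,
              dimnames = list(NULL, sprintf("f%02d", 1:6)))
  y <- rep(c(0L, 1L), 8)
  X[, 1] <- X[, 1] + 2.5 * y
  tab <- feature_table(sprintf("c%02d", 1:16), X, y)
  spec <- classifier_spec("knn", grid = data.frame(k = 3,
                                                   weights = "uniform",
                                                   stringsAsFactors = FALSE))
  w <- capture_warnings(rep <- nested_cv(tab, spec, k_inner = 7L, seed = 3L))
  expect_true(any(grepl("selection folds", w)))
  expect_equal(nrow(rep$knn$folds), 8L)
})

test_that("per-fold F2 recomputed from scores matches the report", {
  tab <- fixture_small_table(n = 48, p = 5, seed = 35)
  spec <- classifier_spec("lr", grid = data.frame(C = 1))
  rep <- nested_cv(tab, spec, seed = 9L, select = FALSE)$lr
  # mean metrics are the unweighted fold means to 1e-12
  for (m in c("f2", "acc", "auc", "precision", "recall"))
    expect_equal(rep$mean[[m]], mean(rep$folds[[m]]), tolerance = 1e-12)
  # F2 is consistent with precision/recall per fold
  with(rep$folds, {
    ok <- precision + recall > 0
    expect_equal(f2[ok],
                 5 * precision[ok] * recall[ok] /
                   (4 * precision[ok] + recall[ok]),
                 tolerance = 1e-12)
  })
})
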