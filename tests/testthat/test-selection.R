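# Feature fusion, train-only standardization, and the two-step consensus
# selection with hand-traced set algebra.

make_fold_result <- function(s_rf, s_xgb, imp_rf, imp_xgb) {
  list(s_rf = s_rf, s_xgb = s_xgb, imp_rf = imp_rf, imp_xgb = imp_xgb)
}

test_that("fusion of aligned groups yields the 136-column table", {
  n <- 4
  ids <- sprintf("c%d", 1:n)
  morph <- matrix(rnorm(n * 25), n,
                  dimnames = list(ids, sprintf("m%02d", 1:25)))
  rad <- matrix(rnorm(n * 107), n,
                dimnames = list(ids, sprintf("r%03d", 1:107)))
  deep <- matrix(rnorm(n * 2), n, dimnames = list(ids, c("score1", "score2")))
  clin <- data.frame(case_id = ids, sex = c("female", "male", "male", "female"),
                     age = c(40, 55, 61, 47), ruptured = c(0, 1, 1, 0))
  tab <- fuse_features(morph, rad, deep, clin)
  expect_equal(ncol(tab$features), 136L)
  expect_equal(tab$labels, c(0L, 1L, 1L, 0L))
  expect_equal(unname(tab$features[, "clin_sex"]), c(0, 1, 1, 0))
  expect_equal(sum(startsWith(colnames(tab$features), "morph_")), 25L)
  expect_equal(sum(startsWith(colnames(tab$features), "rad_")), 107L)
  expect_equal(sum(startsWith(colnames(tab$features), "dl_")), 2L)
  # row alignment survives permuted inputs
  tab2 <- fuse_features(morph, rad[rev(ids), ], deep, clin[c(3, 1, 4, 2), ])
  expect_equal(tab2$features, tab$features)
})

test_that("misaligned case ids raise an alignment error naming the case", {
  ids <- c("a", "b", "c")
  morph <- matrix(0, 3, 25, dimnames = list(ids, sprintf("m%02d", 1:25)))
  rad <- matrix(0, 3, 107, dimnames = list(c("a", "b", "zz"),
                                           sprintf("r%03d", 1:107)))
  deep <- matrix(0, 3, 2, dimnames = list(ids, c("score1", "score2")))
  clin <- data.frame(case_id = ids, sex = "female", age = 50, ruptured = 0)
  err <- tryCatch(fuse_features(morph, rad, deep, clin), error = function(e) e)
  expect_s3_class(err, "anf_alignment_error")
  expect_match(conditionMessage(err), "zz")
})

test_that("standardization uses train moments only and flags constants", {
  ids <- sprintf("c%d", 1:3)
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  rownames(X) <- NULL
  tr <- feature_table(ids, X)
  std <- standardize(tr)
  # population sd of {1,2,3} is sqrt(2/3)
  expect_equal(unname(std$train$features[, "a"]),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(round(unname(std$train$features[, "a"]), 4),
               c(-1.2247, 0, 1.2247))
  expect_true(std$constant[["b"]])
  expect_true(all(std$train$features[, "b"] == 0))
  # self-application: mean 0, population sd 1
  both <- standardize(tr, tr)
  expect_equal(colMeans(both$applied$features), c(a = 0, b = 0),
               tolerance = 1e-9)
  # new data transformed with TRAIN parameters, not its own
  te <- feature_table("x", cbind(a = 7, b = 9))
  app <- standardize(tr, te)$applied
  expect_equal(unname(app$features[, "a"]), (7 - 2) / sqrt(2 / 3),
               tolerance = 1e-12)
})

test_that("per-method selection keeps features above the mean importance", {
  # hand trace: importances (0.5, 0.3, 0.1, 0.1), mean 0.25 -> first two
  imp <- c(f1 = 0.5, f2 = 0.3, f3 = 0.1, f4 = 0.1)
  expect_equal(names(imp)[imp > mean(imp)], c("f1", "f2"))
  # the equivalent hand trace through the real fitter on separable data
  tab <- fixture_small_table(n = 40, p = 6, seed = 41)
  res <- per_fold_select(tab$features, tab$labels, fold_seed = 1L)
  expect_true("f01" %in% res$s_rf)
  expect_true("f01" %in% res$s_xgb)
  expect_true(all(res$imp_rf >= 0) && all(res$imp_xgb >= 0))
  # single-class fold is rejected
  expect_error(per_fold_select(tab$features, rep(1L, 40), fold_seed = 1L),
               class = "anf_stratification_error")
})

test_that("Step 1 merges the per-fold simultaneous selections", {
  fr <- function(rf, xgb) make_fold_result(rf, xgb, NULL, NULL)
  # {a,b} & {b,c} = {b} in all 8 folds
  eight <- replicate(8, fr(c("a", "b"), c("b", "c")), simplify = FALSE)
  expect_equal(step1_union(eight), "b")
  # fold 1 gives {a}, fold 2 gives {c}, others empty
  mixed <- c(list(fr("a", "a"), fr("c", "c")),
             replicate(6, fr("x", "y"), simplify = FALSE))
  expect_setequal(step1_union(mixed), c("a", "c"))
  empty <- replicate(8, fr("x", "y"), simplify = FALSE)
  expect_warning(M <- step1_union(empty), "empty")
  expect_length(M, 0L)
})

test_that("Step 2 ranks accumulated importances and intersects top halves", {
  feats <- c("a", "b", "c", "d")
  fr <- function(imp_rf, imp_xgb)
    make_fold_result(NULL, NULL, imp_rf, imp_xgb)
  # rf order a>b>c>d, xgb order b>a>d>c -> M_r = M_x = {a,b} -> N = {a,b}
  folds <- replicate(2, fr(c(a = 4, b = 3, c = 2, d = 1),
                           c(a = 3, b = 4, c = 1, d = 2)), simplify = FALSE)
  res <- step2_intersect(feats, folds)
  expect_setequal(res$M_r, c("a", "b"))
  expect_setequal(res$M_x, c("a", "b"))
  expect_setequal(res$N, c("a", "b"))
  expect_false(res$fallback)
  # rf order a>b>c>d, xgb order c>d>a>b -> disjoint top halves -> fallback
  folds2 <- list(fr(c(a = 4, b = 3, c = 2, d = 1),
                    c(a = 2, b = 1, c = 4, d = 3)))
  expect_warning(res2 <- step2_intersect(feats, folds2), "union")
  expect_setequal(res2$N, c("a", "b", "c", "d"))
  expect_true(res2$fallback)
  # |M| = 1 collapses to that single feature
  folds3 <- list(fr(c(a = 1), c(a = 1)))
  res3 <- step2_intersect("a", folds3)
  expect_equal(res3$N, "a")
  # set algebra invariants
  for (r in list(res, res2, res3)) {
    expect_true(all(r$M_r %in% r$M) && all(r$M_x %in% r$M))
    expect_equal(length(r$M_r), ceiling(length(r$M) / 2))
    expect_equal(length(r$M_x), ceiling(length(r$M) / 2))
    if (!r$fallback) expect_true(all(r$N %in% intersect(r$M_r, r$M_x)))
  }
})

test_that("accumulated-importance ties break lexicographically", {
  fr <- make_fold_result(NULL, NULL,
                         c(a = 1, b = 1, c = 1, d = 1),
                         c(a = 1, b = 1, c = 1, d = 1))
  res <- step2_intersect(c("d", "b", "a", "c"), list(fr))
  expect_equal(sort(res$M_r), c("a", "b"))
  expect_equal(sort(res$M_x), c("a", "b"))
})

test_that("full selection is deterministic and finds a planted feature", {
  tab <- fixture_small_table(n = 48, p = 12, seed = 43)
  fa <- stratified_folds(tab$labels, k = 8L, seed = 2L)
  r1 <- select_features(tab, fa, seed = 10L)
  r2 <- select_features(tab, fa, seed = 10L)
  expect_identical(r1[c("M", "M_r", "M_x", "N")],
                   r2[c("M", "M_r", "M_x", "N")])
  expect_true("f01" %in% r1$N)
})

test_that("selection never reads the held-out fold (leakage instrumentation)", {
  tab <- fixture_small_table(n = 48, p = 8, seed = 44)
  fa <- stratified_folds(tab$labels, k = 8L, seed = 3L)
  base <- select_features(tab, fa, seed = 11L)
  # train only on folds != 1 when fold 1 is held out: mutate the fold-1 rows
  # wildly; the fold-1 training split result must be unchanged
  mutated <- tab$features
  mutated[fa == 1L, ] <- mutated[fa == 1L, ] + 1000
  tab_mut <- feature_table(tab$ids, mutated, tab$labels)
  tr <- which(fa != 1L)
  sub <- function(t) feature_table(t$ids[tr], t$features[tr, , drop = FALSE],
                                   t$labels[tr])
  std_a <- standardize(sub(tab))
  std_b <- standardize(sub(tab_mut))
  sel_a <- per_fold_select(std_a$train$features, std_a$train$labels, 99L)
  sel_b <- per_fold_select(std_b$train$features, std_b$train$labels, 99L)
  expect_identical(sel_a, sel_b)
})
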